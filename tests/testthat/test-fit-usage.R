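make_usage_data <- function(n_exons = 20, S = 4, A = c(-0.5, 0.5, 1, -1),
                            sd = 0.25, seed = 7) {
  set.seed(seed)
  sizes <- sample(2:3, n_exons, TRUE)
  P <- sum(sizes)
  exon <- rep(sprintf("ex%03d", seq_len(n_exons)), sizes)
  N <- rpois(P, 1.5)
  ef <- factor(exon, levels = unique(exon))
  Nc <- N - ave(N, ef)
  y <- outer(Nc, A) + rnorm(P) +
    matrix(rnorm(n_exons * S, 0, 0.5), n_exons, S)[as.integer(ef), ] +
    matrix(rnorm(P * S, 0, sd), P, S)
  colnames(y) <- paste0("s", seq_len(S))
  list(y = y, exon = exon, N = N, A = A)
}

# Explicit normal-equations OLS with indicator covariates; the activity
# block is identified up to a common shift, resolved by centering.
ols_oracle <- function(y, exon, N) {
  P <- nrow(y)
  S <- ncol(y)
  samp <- factor(rep(seq_len(S), each = P))
  site <- factor(rep(seq_len(P), S))
  se <- factor(paste(rep(exon, S), samp))
  X <- cbind(stats::model.matrix(~ 0 + samp) * rep(N, S),
             stats::model.matrix(~ 0 + site),
             stats::model.matrix(~ 0 + se))
  beta <- MASS::ginv(crossprod(X)) %*% crossprod(X, as.vector(y))
  A <- beta[seq_len(S)]
  A - mean(A)
}

test_that("double-centered fit equals explicit normal-equations OLS", {
  d <- make_usage_data(20, 4, seed = 101)
  fit <- fit_usage_activity(d$y, d$exon, d$N)
  expect_lt(max(abs(unname(fit$A) - ols_oracle(d$y, d$exon, d$N))), 1e-8)
  expect_equal(sum(fit$A), 0, tolerance = 1e-12)
})

test_that("usage identical across samples gives zero activities", {
  d <- make_usage_data(15, 3, A = c(0, 0, 0), sd = 0)
  y <- matrix(d$y[, 1], nrow(d$y), 3)  # no sample variation at all
  fit <- fit_usage_activity(y, d$exon, d$N)
  expect_equal(unname(fit$A), c(0, 0, 0), tolerance = 1e-12)
})

test_that("nuisance shifts leave the activities unchanged", {
  d <- make_usage_data(20, 4, seed = 5)
  fit0 <- fit_usage_activity(d$y, d$exon, d$N)
  # site-specific constants (c_p direction)
  y1 <- d$y + rnorm(nrow(d$y))
  expect_equal(fit_usage_activity(y1, d$exon, d$N)$A, fit0$A,
               tolerance = 1e-10)
  # (sample, exon)-specific constants (c_{s,e} direction)
  ef <- factor(d$exon, levels = unique(d$exon))
  shift <- matrix(rnorm(nlevels(ef) * 4), nlevels(ef), 4)
  y2 <- d$y + shift[as.integer(ef), ]
  expect_equal(fit_usage_activity(y2, d$exon, d$N)$A, fit0$A,
               tolerance = 1e-10)
})

test_that("doubling the evidence halves the activities", {
  d <- make_usage_data(20, 4, seed = 6)
  f1 <- fit_usage_activity(d$y, d$exon, d$N)
  f2 <- fit_usage_activity(d$y, d$exon, 2 * d$N)
  expect_equal(unname(f2$A), unname(f1$A) / 2, tolerance = 1e-10)
})

test_that("constant evidence within every exon is uninformative", {
  d <- make_usage_data(15, 3, A = c(0, 0, 0))
  ef <- factor(d$exon, levels = unique(d$exon))
  N <- as.integer(ef)  # varies across exons, constant within
  fit <- fit_usage_activity(d$y, ef, N)
  expect_identical(fit$flag, "uninformative")
  expect_equal(unname(fit$A), c(0, 0, 0))
})

test_that("planted poly(A) activities are recovered from the simulator", {
  sim <- simulate_pas_dataset(sim_config(
    n_pas_exons = 300, n_samples = 4,
    conditions = c("CTRL", "CTRL", "KD", "KD"),
    activity = c(CTRL = -1, KD = 1), plant_site = "PAS",
    plant_window = c(-50, 0), plant_rate = 0.5, noise_sd = 0.25,
    seed = 99))
  pas <- sim$pas
  N <- sim$truth$N[pas$sites$site_id]
  fit <- fit_usage_activity(log2(pas$u), pas$exon_id, N)
  expect_gte(cor(sim$truth$A, fit$A), 0.9)
  expect_true(all(sign(fit$A) == sign(sim$truth$A)))
})

test_that("under the null the usage z-scores are calibrated", {
  set.seed(77)
  d <- make_usage_data(120, 4, A = rep(0, 4), sd = 0.4, seed = 77)
  zs <- replicate(200, {
    N <- rpois(nrow(d$y), 1.5)
    fit_usage_activity(d$y, d$exon, N)$Z
  })
  expect_lt(abs(mean(zs)), 0.1)
  expect_gt(sd(zs), 0.8)
  expect_lt(sd(zs), 1.2)
})

test_that("z-score tables track dropped groups and flags", {
  d <- make_usage_data(20, 2, A = c(-0.3, 0.3), seed = 8)
  win <- data.frame(site_type = "PAS", start = -25, end = 25,
                    window_id = "PAS_-25_+25")
  N <- d$N
  N[d$exon == d$exon[1]] <- NA  # mask a whole exon group
  fit <- fit_usage_activity(d$y, d$exon, N, motif_id = "m1", window = win)
  expect_lt(fit$n_events, nrow(d$y))
  fits <- c(list(fit), lapply(2:23, function(k) fit_usage_activity(
    d$y, d$exon, d$N, motif_id = paste0("m", k), window = win)))
  tab <- activity_zscore_table(fits)
  expect_identical(nrow(tab), 46L)  # 23 motifs x 2 samples
  uninf <- fit_usage_activity(d$y, d$exon,
                              as.integer(factor(d$exon,
                                                levels = unique(d$exon))),
                              motif_id = "flat", window = win)
  tab2 <- activity_zscore_table(list(uninf))
  expect_true(all(is.na(tab2$Z)))
})
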