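#' Renormalize activity z-scores against a Gaussian-mixture background
#'
#' Most motifs in a window are not regulators, so across motifs the raw
#' z-scores form a dominant (null) bulk plus a small signal component. A
#' two-component univariate Gaussian mixture is fitted by EM with
#' deterministic initialization (component means at the 25th and 75th
#' percentiles, equal weights, both standard deviations at the pooled sd;
#' at most 500 iterations or a log-likelihood change below `1e-10`). The
#' component with the larger weight is taken as the null, and z-scores are
#' standardized against it: `z_renorm = (z - mu0) / sigma0`, with
#' two-sided standard-normal p-values.
#'
#' With fewer than `min_n` finite z-scores the mixture is not
#' identifiable; the raw z-scores are then treated as standard normal with
#' a warning. Zero-variance input is flagged degenerate and gets `p = 1`.
#'
#' @param z numeric vector of z-scores across motifs for one
#'   (site type, window, sample) context; `NA` allowed.
#' @param min_n minimum number of finite values for the mixture fit.
#' @return list with `z_renorm`, `p` (aligned with `z`), `mu0`, `sigma0`,
#'   `weights`, `means`, `sds` of the fitted components, and `flag`
#'   (`"gmm"`, `"fallback"`, `"degenerate"`).
#' @export
renormalize_zscores <- function(z, min_n = 50) {
  fin <- is.finite(z)
  out <- list(z_renorm = rep(NA_real_, length(z)),
              p = rep(NA_real_, length(z)),
              mu0 = NA_real_, sigma0 = NA_real_, weights = NULL,
              means = NULL, sds = NULL, flag = "gmm")
  x <- z[fin]
  if (length(x) == 0L) return(out)
  if (sd(x) < 1e-12) {
    out$p[fin] <- 1
    out$z_renorm[fin] <- 0
    out$flag <- "degenerate"
    return(out)
  }
  if (sum(fin) < min_n) {
    warning("only ", sum(fin), " finite z-scores; using raw z as ",
            "standard normal", call. = FALSE)
    out$z_renorm[fin] <- x
    out$p[fin] <- 2 * pnorm(-abs(x))
    out$mu0 <- 0
    out$sigma0 <- 1
    out$flag <- "fallback"
    return(out)
  }
  fit <- gmm2_em(x)
  # A two-component mixture is unidentifiable when the z-scores are a
  # single Gaussian bulk (the EM then splits the bulk symmetrically);
  # select between the one-Gaussian and two-component fits by BIC so the
  # null component is only separated when the data support it.
  ll1 <- sum(dnorm(x, mean(x), sd(x) * sqrt(1 - 1 / length(x)),
                   log = TRUE))
  bic1 <- -2 * ll1 + 2 * log(length(x))
  bic2 <- -2 * fit$loglik + 5 * log(length(x))
  if (bic1 <= bic2) {
    mu0 <- mean(x)
    s0 <- sd(x)
    fit <- list(weights = 1, means = mu0, sds = s0)
  } else {
    null_k <- which.max(fit$weights)
    mu0 <- fit$means[null_k]
    s0 <- fit$sds[null_k]
  }
  out$z_renorm[fin] <- (x - mu0) / s0
  out$p[fin] <- 2 * pnorm(-abs(out$z_renorm[fin]))
  out$mu0 <- mu0
  out$sigma0 <- s0
  out$weights <- fit$weights
  out$means <- fit$means
  out$sds <- fit$sds
  out
}

# Deterministic 2-component univariate Gaussian mixture EM.
gmm2_em <- function(x, max_iter = 500, tol = 1e-10) {
  mu <- unname(quantile(x, c(0.25, 0.75)))
  s <- rep(max(sd(x), 1e-8), 2)
  w <- c(0.5, 0.5)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(x, mu[1], s[1])
    d2 <- w[2] * stats::dnorm(x, mu[2], s[2])
    tot <- d1 + d2
    tot[tot < 1e-300] <- 1e-300
    ll <- sum(log(tot))
    r <- d1 / tot
    n1 <- sum(r)
    n2 <- length(x) - n1
    if (n1 < 1e-8 || n2 < 1e-8) break
    mu <- c(sum(r * x) / n1, sum((1 - r) * x) / n2)
    s <- sqrt(pmax(c(sum(r * (x - mu[1])^2) / n1,
                     sum((1 - r) * (x - mu[2])^2) / n2), 1e-12))
    w <- c(n1, n2) / length(x)
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(weights = w, means = mu, sds = s, loglik = ll)
}

#' Bonferroni correction
#' @param p raw p-value(s) in `[0, 1]`.
#' @param m number of tests, `m >= 1`.
#' @return `min(1, m * p)`, vectorized.
#' @export
bonferroni <- function(p, m) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p must be in [0, 1]",
                                             call. = FALSE)
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  pmin(1, m * p)
}

#' Renormalize and annotate a z-score table
#'
#' Fits the mixture background separately per (site type, window, sample)
#' context across motifs, attaches renormalized z-scores and p-values,
#' Bonferroni-corrects with the multiple-testing universe
#' `m = n_motifs x n_(site type, window) combinations x n_samples` — every
#' annotated impact-map cell is a test — and flags significance at level
#' `alpha`.
#'
#' @param ztab long-format table from [activity_zscore_table()]
#'   (tables from both processing models can be `rbind`-ed first).
#' @param alpha significance level on the Bonferroni-corrected p-values.
#' @param min_n mixture fallback threshold, see [renormalize_zscores()].
#' @return the input table with columns `z_renorm`, `p`, `p_bonf`,
#'   `significant` added; attribute `"m"` records the testing universe.
#' @export
significance_table <- function(ztab, alpha = 0.05, min_n = 50) {
  ztab$z_renorm <- NA_real_
  ztab$p <- NA_real_
  ctx <- interaction(ztab$site_type, ztab$window_start, ztab$window_end,
                     ztab$sample, drop = TRUE)
  for (g in levels(ctx)) {
    idx <- which(ctx == g)
    rn <- renormalize_zscores(ztab$Z[idx], min_n = min_n)
    ztab$z_renorm[idx] <- rn$z_renorm
    ztab$p[idx] <- rn$p
  }
  n_motifs <- length(unique(ztab$motif_id))
  n_windows <- nrow(unique(ztab[, c("site_type", "window_start",
                                    "window_end")]))
  n_samples <- length(unique(ztab$sample))
  m <- n_motifs * n_windows * n_samples
  ztab$p_bonf <- ifelse(is.na(ztab$p), NA_real_, bonferroni(
    ifelse(is.na(ztab$p), 0, ztab$p), m))
  ztab$significant <- !is.na(ztab$p_bonf) & ztab$p_bonf < alpha
  attr(ztab, "m") <- m
  attr(ztab, "alpha") <- alpha
  ztab
}

#' Combined z-score of one motif's impact map
#'
#' Mean, over the site types analyzed for the motif, of the maximum
#' absolute renormalized z-score across that site type's windows and
#' samples. An all-`NA` map scores 0.
#'
#' @param map rows of a [significance_table()] for one motif.
#' @return non-negative scalar.
#' @export
combined_zscore <- function(map) {
  per_site <- tapply(abs(map$z_renorm), map$site_type,
                     function(v) if (all(is.na(v))) NA_real_ else
                       max(v, na.rm = TRUE))
  per_site <- per_site[!is.na(per_site)]
  if (length(per_site) == 0L) return(0)
  mean(per_site)
}

#' Rank motifs by combined z-score
#'
#' @param sig a [significance_table()].
#' @return data.frame with one row per motif: `motif_id`, `combined_z`,
#'   `rank` (descending combined z, ties broken lexicographically by motif
#'   id), `n_significant`, and the best cell (`best_site`, `best_window`,
#'   `best_sample`, `best_z_renorm`).
#' @export
rank_motifs <- function(sig) {
  motifs <- sort(unique(sig$motif_id))
  rows <- lapply(motifs, function(m) {
    sub <- sig[sig$motif_id == m, , drop = FALSE]
    cz <- combined_zscore(sub)
    best <- which.max(abs(sub$z_renorm))
    if (length(best) == 0L || all(is.na(sub$z_renorm))) {
      best_site <- NA_character_; best_win <- NA_character_
      best_sample <- NA_character_; best_zr <- NA_real_
    } else {
      best_site <- sub$site_type[best]
      best_win <- sprintf("%+d_%+d", sub$window_start[best],
                          sub$window_end[best])
      best_sample <- sub$sample[best]
      best_zr <- sub$z_renorm[best]
    }
    data.frame(motif_id = m, combined_z = cz,
               n_significant = sum(sub$significant, na.rm = TRUE),
               best_site = best_site, best_window = best_win,
               best_sample = best_sample, best_z_renorm = best_zr,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$combined_z, out$motif_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("motif_id", "combined_z", "rank", "n_significant", "best_site",
          "best_window", "best_sample", "best_z_renorm")]
}

#' Impact map of one motif
#'
#' The grid of raw and renormalized z-scores with significance flags,
#' ordered site type / window / sample — the tabular form of the impact
#' map heatmap (negative = repressive, positive = activating; significant
#' cells are the asterisked ones).
#'
#' @param sig a [significance_table()].
#' @param motif_id motif to extract.
#' @return data.frame subset of `sig` for the motif.
#' @export
impact_map <- function(sig, motif_id) {
  sub <- sig[sig$motif_id == motif_id, , drop = FALSE]
  if (nrow(sub) == 0L) stop("motif '", motif_id, "' not in table",
                            call. = FALSE)
  sub <- sub[order(sub$site_type, sub$window_start, sub$sample), ,
             drop = FALSE]
  rownames(sub) <- NULL
  sub
}

#' Lowest significant rank of any PWM mapped to a perturbed RBP
#'
#' Used to check whether the motif catalog recovers a perturbed regulator:
#' among the PWMs assigned to the RBP that have at least one
#' Bonferroni-significant cell, return the minimum (best) rank.
#'
#' @param ranked output of [rank_motifs()].
#' @param mapping data.frame with columns `rbp` and `pwm_id`.
#' @param rbp the perturbed RBP name.
#' @return integer rank, or `NA` (with a warning) when the RBP is unmapped
#'   or no mapped PWM is significant anywhere.
#' @export
rank_for_perturbed_rbp <- function(ranked, mapping, rbp) {
  pwms <- mapping$pwm_id[mapping$rbp == rbp]
  if (length(pwms) == 0L) {
    warning("RBP '", rbp, "' absent from mapping", call. = FALSE)
    return(NA_integer_)
  }
  sub <- ranked[ranked$motif_id %in% pwms & ranked$n_significant > 0, ,
                drop = FALSE]
  if (nrow(sub) == 0L) return(NA_integer_)
  min(sub$rank)
}
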