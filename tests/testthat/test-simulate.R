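test_that("simulation configs validate their inputs", {
  expect_error(sim_config(), "seed is mandatory")
  expect_error(sim_config(n_samples = 4, conditions = c("a", "b"),
                          seed = 1), "length n_samples")
  expect_error(sim_config(activity = c(X = 1), seed = 1), "named by")
  expect_error(sim_config(plant_rate = 2, seed = 1), "plant_rate")
})

test_that("generators are pure functions of their config", {
  cfg <- sim_preset("pentaU_repressor", seed = 7, n_exons = 60)
  s1 <- simulate_splicing_dataset(cfg)
  s2 <- simulate_splicing_dataset(cfg)
  expect_identical(as.character(s1$genome), as.character(s2$genome))
  expect_identical(s1$junction_counts, s2$junction_counts)
  expect_identical(s1$truth, s2$truth)
  cfg_p <- sim_config(n_pas_exons = 30, n_samples = 4,
                      conditions = rep(c("A", "B"), 2),
                      activity = c(A = -1, B = 1), plant_site = "PAS",
                      seed = 7)
  p1 <- simulate_pas_dataset(cfg_p)
  p2 <- simulate_pas_dataset(cfg_p)
  expect_identical(p1$site_counts, p2$site_counts)
  # different seed changes the data
  s3 <- simulate_splicing_dataset(
    sim_preset("pentaU_repressor", seed = 8, n_exons = 60))
  expect_false(identical(as.character(s1$genome),
                         as.character(s3$genome)))
})

test_that("the global RNG state is untouched by generators", {
  set.seed(123)
  before <- .Random.seed
  invisible(simulate_splicing_dataset(
    sim_preset("null", seed = 4, n_exons = 20)))
  expect_identical(.Random.seed, before)
})

test_that("emitted junction tables round-trip through event selection", {
  sim <- simulate_splicing_dataset(
    sim_preset("pentaU_repressor", seed = 13, n_exons = 80))
  ev <- sim$events
  expect_identical(nrow(ev$events), 80L)
  # inclusion fractions reproduce the binomial draws exactly
  i <- (ev$incl_up + ev$incl_down) / 2
  expect_equal(unname(ev$f), unname(i / (i + ev$skip)))
  # planted motif counts recomputed from the genome match the truth
  sites <- site_table(ev, "SS3")
  win <- data.frame(site_type = "SS3", start = -50, end = 0,
                    window_id = "w")
  seqs <- extract_window_sequence(sim$genome, sites, win)
  N <- vapply(seqs, count_motif, 0.0, motif = kmer_motif("UUUUU"))
  expect_equal(unname(N), unname(sim$truth$N[names(seqs)]))
})

test_that("emitted genome FASTA round-trips losslessly", {
  sim <- simulate_splicing_dataset(
    sim_preset("null", seed = 21, n_exons = 10))
  fa <- tempfile(fileext = ".fa")
  Biostrings::writeXStringSet(sim$genome, fa)
  back <- load_genome(fa)
  expect_identical(as.character(back), as.character(sim$genome))
})

test_that("a null simulation carries no association", {
  sim <- simulate_splicing_dataset(
    sim_preset("null", seed = 31, n_exons = 2000))
  ev <- sim$events
  # correlation between any k-mer count near the 3'SS and logit(f)
  sites <- site_table(ev, "SS3")
  win <- data.frame(site_type = "SS3", start = -50, end = 0,
                    window_id = "w")
  seqs <- extract_window_sequence(sim$genome, sites, win)
  N <- vapply(seqs, count_motif, 0.0, motif = kmer_motif("UUUU"))
  f <- rowMeans(ev$f)
  lg <- qlogis(pmin(pmax(f, 0.02), 0.98))
  expect_lt(abs(cor(N[ev$events$event_id], lg)), 0.05)
})

test_that("zero planting rate leaves only background occurrences", {
  cfg <- sim_preset("pentaU_repressor", seed = 41, n_exons = 400,
                    plant_rate = 0)
  sim <- simulate_splicing_dataset(cfg)
  # background penta-U in a 50-nt window: ~46/1024 per event
  expect_lt(mean(sim$truth$N), 0.1)
  expect_false(any(sim$truth$planted))
})

test_that("poly(A) tables are valid usage simplices", {
  sim <- simulate_pas_dataset(sim_config(
    n_pas_exons = 50, n_samples = 4, conditions = rep(c("A", "B"), 2),
    activity = c(A = -1, B = 1), plant_site = "PAS", seed = 3))
  u <- sim$pas$u
  sums <- tapply(u[, 1], sim$pas$exon_id, sum)
  expect_equal(as.vector(sums), rep(1, length(sums)), tolerance = 1e-9)
  expect_true(all(u > 0))
  # noiseless, activity-free config: usage constant across samples
  sim0 <- simulate_pas_dataset(sim_config(
    n_pas_exons = 30, n_samples = 3, conditions = c("A", "A", "A"),
    motif = NULL, noise_sd = 0, pas_depth = 1e6, seed = 5))
  expect_lt(max(apply(sim0$pas$u, 1, sd)), 0.01)
})

test_that("coverage simulation is deterministic and fold-responsive", {
  sites <- data.frame(site_id = c("a", "b"), chrom = c("c1", "c1"),
                      strand = "+", position = c(500, 1500))
  lens <- c(c1 = 2000L)
  c1 <- simulate_coverage(lens, sites, targets = "a", fold = 3,
                          seed = 11)
  c2 <- simulate_coverage(lens, sites, targets = "a", fold = 3,
                          seed = 11)
  expect_identical(as.numeric(c1$fg$coverage$c1),
                   as.numeric(c2$fg$coverage$c1))
  c_flat <- simulate_coverage(lens, sites, targets = "a", fold = 1,
                              seed = 11)
  expect_identical(as.numeric(c_flat$fg$coverage$c1),
                   as.numeric(c_flat$fg$coverage$c1))
})
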