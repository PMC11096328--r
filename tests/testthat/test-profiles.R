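# Common toy site layout: sites on two 20-knt chromosomes, spaced
# well beyond the profile half-widths used below.
toy_sites <- function(n = 60) {
  data.frame(site_id = sprintf("site%03d", seq_len(n)),
             chrom = rep(c("c1", "c2"), length.out = n),
             strand = rep(c("+", "-"), each = 2, length.out = n),
             position = rep(seq(500, 19500, length.out = ceiling(n / 2)),
                            each = 2, length.out = n),
             stringsAsFactors = FALSE)
}

test_that("target selection is deterministic and direction-aware", {
  set.seed(41)
  deltas <- data.frame(site_id = sprintf("s%04d", 1:1500),
                       delta = rnorm(1500))
  sel <- select_targets(deltas, "up", n_top = 200, n_least = 1000)
  expect_identical(nrow(sel$targets), 200L)
  expect_identical(nrow(sel$least_changing), 1000L)
  expect_gte(min(sel$targets$delta),
             max(deltas$delta[!deltas$site_id %in% sel$targets$site_id]))
  expect_lte(max(abs(sel$least_changing$delta)),
             min(abs(deltas$delta[!deltas$site_id %in%
                                    c(sel$targets$site_id,
                                      sel$least_changing$site_id)])))
  # flipping the direction on an antisymmetric toy mirrors the targets
  anti <- data.frame(site_id = sprintf("s%04d", 1:400),
                     delta = c(seq(-1, -0.01, length.out = 200),
                               seq(0.01, 1, length.out = 200)))
  up <- select_targets(anti, "up", 100, 100)$targets
  dn <- select_targets(anti, "down", 100, 100)$targets
  expect_equal(sort(up$delta), sort(-dn$delta))
  expect_error(select_targets(anti, "up", 300, 200), "at least")
})

test_that("identical tracks give a flat unit profile", {
  sites <- toy_sites()
  lens <- c(c1 = 20000L, c2 = 20000L)
  cov <- simulate_coverage(lens, sites, targets = character(0),
                           fold = 1, seed = 5)
  prof <- ratio_profile(cov$fg, cov$fg, sites, halfwidth = 100)
  expect_equal(prof$ratio, rep(1, 201))
  # constant profiles are unchanged by smoothing
  expect_equal(rbpimpact:::running_mean(rep(3.5, 50), 5), rep(3.5, 50))
})

test_that("planted enrichment produces a localized smoothed peak", {
  sites <- toy_sites()
  lens <- c(c1 = 20000L, c2 = 20000L)
  cov <- simulate_coverage(lens, sites, targets = sites$site_id,
                           enrich_window = c(-50, 0), fold = 3,
                           rate = 20, seed = 6)
  prof <- ratio_profile(cov$fg, cov$bg, sites, halfwidth = 150, smooth = 5)
  # library-size normalization makes the flat region sit slightly below 1
  inside <- prof$ratio[prof$offset >= -40 & prof$offset < -10]
  outside <- prof$ratio[abs(prof$offset) > 80]
  expect_gt(min(inside), 2 * max(outside))
  expect_lt(max(abs(outside - mean(outside))), 0.2)
  # peak location: maximum inside the planted window
  expect_true(prof$offset[which.max(prof$ratio)] >= -50 &&
                prof$offset[which.max(prof$ratio)] <= 0)
})

test_that("scaling both libraries leaves the profile unchanged", {
  sites <- toy_sites(20)
  lens <- c(c1 = 20000L, c2 = 20000L)
  cov <- simulate_coverage(lens, sites, targets = sites$site_id,
                           fold = 2, rate = 10, seed = 7)
  p1 <- ratio_profile(cov$fg, cov$bg, sites, halfwidth = 80)
  fg2 <- coverage_track(cov$fg$coverage,
                        library_size = cov$fg$library_size * 10)
  # scaling the library size alone rescales; scaling coverage + library
  # together cancels
  fg3 <- coverage_track(
    as_rle_list(lapply(cov$fg$coverage, function(r) r * 10)),
    library_size = cov$fg$library_size * 10)
  p3 <- ratio_profile(fg3, cov$bg, sites, halfwidth = 80)
  expect_equal(p3$ratio, p1$ratio, tolerance = 1e-9)
})

test_that("the background band is seed-deterministic and tightens", {
  sites <- toy_sites(40)
  lens <- c(c1 = 20000L, c2 = 20000L)
  cov <- simulate_coverage(lens, sites, targets = character(0),
                           fold = 1, rate = 10, seed = 8)
  b1 <- background_band(sites, cov$fg, cov$bg, draws = 30,
                        draw_size = 20, seed = 17, halfwidth = 60)
  b2 <- background_band(sites, cov$fg, cov$bg, draws = 30,
                        draw_size = 20, seed = 17, halfwidth = 60)
  expect_identical(b1, b2)
  b_wide <- background_band(sites, cov$fg, cov$bg, draws = 30,
                            draw_size = 5, seed = 17, halfwidth = 60)
  b_narrow <- background_band(sites, cov$fg, cov$bg, draws = 30,
                              draw_size = 40, seed = 17, halfwidth = 60)
  expect_lt(mean(b_narrow$bg_sd), mean(b_wide$bg_sd))
  # identical coverage at all sites: zero band width
  const <- coverage_track(as_rle_list(
    lapply(lens, function(L) S4Vectors::Rle(5L, L))))
  b0 <- background_band(sites, const, const, draws = 10, draw_size = 10,
                        seed = 1, halfwidth = 30)
  expect_equal(b0$bg_sd, rep(0, 61))
})

test_that("bedGraph round-trips preserve coverage", {
  sites <- toy_sites(10)
  lens <- c(c1 = 20000L, c2 = 20000L)
  cov <- simulate_coverage(lens, sites, targets = sites$site_id,
                           fold = 3, rate = 8, seed = 9)
  bg_file <- tempfile(fileext = ".bedgraph")
  write_bedgraph(cov$fg, bg_file)
  back <- coverage_track(bg_file)
  p1 <- ratio_profile(cov$fg, cov$bg, sites, halfwidth = 50)
  p2 <- ratio_profile(back, cov$bg, sites, halfwidth = 50)
  expect_equal(p2$ratio, p1$ratio, tolerance = 1e-9)
})
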