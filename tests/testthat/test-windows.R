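test_that("window tiling matches the closed-form counts", {
  sch <- region_scheme(ss3 = c(300, 100), window_width = 50, slide = 25)
  w <- generate_windows(sch, "SS3")
  expect_identical(nrow(w), 15L)
  expect_equal(w$start[1], -300)
  expect_equal(w$end[1], -250)
  expect_equal(w$start[15], 50)
  expect_equal(w$end[15], 100)
  expect_true(any(w$start == -25 & w$end == 25))  # central window
  # high-resolution mode
  sch2 <- region_scheme(ss3 = c(100, 100), window_width = 20, slide = 10)
  expect_identical(nrow(generate_windows(sch2, "SS3")), 19L)
  expect_error(region_scheme(ss3 = c(30, 100)), "window wide")
  expect_error(region_scheme(slide = 60), "slide")
})

test_that("off-grid central windows are inserted when requested", {
  sch <- region_scheme(ss3 = c(60, 60), window_width = 50, slide = 20,
                       include_central = TRUE)
  w <- generate_windows(sch, "SS3")
  expect_true(any(w$start == -25 & w$end == 25))
  expect_identical(w$start, sort(w$start))
})

test_that("sequence extraction is strand-aware and mask-aware", {
  # chromosome: positions 1..40
  genome <- Biostrings::DNAStringSet(c(chr = "ACGTACGTACGTACGTACGTAAAATTTTCCCCGGGGACGT"))
  sites <- data.frame(event_id = c("plus", "minus"), chrom = "chr",
                      strand = c("+", "-"), anchor = c(21, 20),
                      off_lo = -Inf, off_hi = Inf)
  win <- list(start = 0, end = 4)
  seqs <- extract_window_sequence(genome, sites, win)
  expect_identical(unname(seqs["plus"]), "AAAA")  # positions 21-24
  # minus: sense offsets 0..3 = genomic 20,19,18,17 complemented
  expect_identical(unname(seqs["minus"]),
                   rna_revcomp(dna_to_rna("ACGT")))
  # upstream window
  win2 <- list(start = -4, end = 0)
  seqs2 <- extract_window_sequence(genome, sites, win2)
  expect_identical(unname(seqs2["plus"]), dna_to_rna("ACGT"))  # 17-20
  # mask: window beyond allowed offsets
  sites$off_hi <- 2
  expect_true(all(is.na(extract_window_sequence(genome, sites, win))))
  # off-chromosome mask
  sites$off_hi <- Inf
  sites$anchor <- c(39, 2)
  expect_true(all(is.na(extract_window_sequence(genome, sites, win))))
  expect_error(extract_window_sequence(
    genome, transform(sites, chrom = "chrX"), win), "missing from FASTA")
})

test_that("k-mer counting counts overlapping occurrences", {
  expect_equal(count_motif("UUUUUU", kmer_motif("UUU")), 4)
  expect_equal(count_motif("ACGUACGU", kmer_motif("ACGU")), 2)
  expect_equal(count_motif("AC", kmer_motif("ACG")), 0)
  expect_error(count_motif("ACGT", kmer_motif("ACG")), "outside")
})

test_that("PWM evidence follows the binding-site posterior formula", {
  m <- one_hot_pwm("ACGU")
  # exactly one match, rho = 0.01
  expect_equal(count_motif("ACGUCCCC", m, prior = 0.01),
               0.01 / (0.01 + 0.99 * 0.25^4))
  # no match: one-hot product is zero everywhere
  expect_equal(count_motif("CCCCCCCC", m), 0)
  # sequence shorter than the motif
  expect_equal(count_motif("AC", m), 0)
  # monotone in the prior
  set.seed(9)
  seqs <- vapply(1:5, function(i)
    paste(sample(c("A", "C", "G", "U"), 30, TRUE), collapse = ""), "")
  soft <- pwm("soft", matrix(c(0.4, 0.3, 0.2, 0.1), 4, 4, byrow = TRUE))
  for (s in seqs) {
    ev <- vapply(c(0.001, 0.01, 0.1, 0.5), function(r)
      count_motif(s, soft, prior = r), 0.0)
    expect_true(all(diff(ev) > 0))
  }
})

test_that("count matrices agree with a naive scan and tile completely", {
  set.seed(21)
  genome <- Biostrings::DNAStringSet(c(g = paste(
    sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")))
  sites <- data.frame(event_id = c("a", "b"), chrom = "g",
                      strand = c("+", "-"), anchor = c(200, 300),
                      off_lo = -Inf, off_hi = Inf)
  wins <- generate_windows(region_scheme(ss3 = c(100, 50)), "SS3")
  kms <- enumerate_kmers(3, 3)
  cm <- build_count_matrix(genome, sites, wins, kms)
  for (w in seq_len(nrow(wins))) {
    seqs <- extract_window_sequence(genome, sites, wins[w, ])
    # sum over the full k-mer universe equals W - k + 1
    expect_equal(unname(rowSums(cm$N[[w]])), rep(48, 2))
    # spot-check against the naive per-position scan
    for (id in c("AAA", "CGU", "UUU")) {
      naive <- vapply(seqs, function(s) {
        st <- seq_len(nchar(s) - 2)
        sum(substring(s, st, st + 2) == id)
      }, 0.0)
      expect_equal(unname(cm$N[[w]][, id]), unname(naive))
    }
  }
})

test_that("minus-strand counting equals counting the reverse complement", {
  set.seed(22)
  raw <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  genome <- Biostrings::DNAStringSet(c(g = raw))
  sites <- data.frame(event_id = "m", chrom = "g", strand = "-",
                      anchor = 120, off_lo = -Inf, off_hi = Inf)
  win <- list(start = -30, end = 20)
  seq_minus <- extract_window_sequence(genome, sites, win)
  # construct the same window by hand on the plus strand and flip
  gslice <- substr(raw, 120 - 20 + 1, 120 + 30)
  expect_identical(unname(seq_minus), rna_revcomp(dna_to_rna(gslice)))
  for (k in c("AAG", "UGC")) {
    expect_equal(count_motif(unname(seq_minus), kmer_motif(k)),
                 count_motif(rna_revcomp(dna_to_rna(gslice)),
                             kmer_motif(k)))
  }
})

test_that("masked cells are missing, not zero", {
  genome <- Biostrings::DNAStringSet(c(g = paste(rep("ACGT", 250),
                                                 collapse = "")))
  sites <- data.frame(event_id = c("short", "long"), chrom = "g",
                      strand = "+", anchor = c(500, 500),
                      off_lo = -300, off_hi = c(40, 100))
  wins <- data.frame(site_type = "SS3", start = 0, end = 50,
                     window_id = "SS3_+0_+50")
  cm <- build_count_matrix(genome, sites, wins,
                           motif_set(list(kmer_motif("ACG"))))
  expect_true(is.na(cm$N[[1]]["short", "ACG"]))
  expect_false(is.na(cm$N[[1]]["long", "ACG"]))
})
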