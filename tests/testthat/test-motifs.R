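test_that("total entropy matches closed-form values", {
  expect_equal(total_entropy(one_hot_pwm("ACGU")), 0)
  expect_equal(total_entropy(uniform_pwm(6)), 12)
  expect_equal(total_entropy(pwm("half", matrix(c(0.5, 0.5, 0, 0), 1))), 1)
  # general bound: 0 <= entropy <= 2L
  set.seed(5)
  for (i in 1:20) {
    L <- sample(1:10, 1)
    m <- matrix(rgamma(4 * L, 1), L, 4)
    m <- m / rowSums(m)
    e <- total_entropy(pwm("r", m))
    expect_gte(e, 0)
    expect_lte(e, 2 * L)
  }
})

test_that("invalid matrices are rejected", {
  expect_error(pwm("bad", matrix(c(0.5, 0.2, 0.2, 0.2), 1)), "sum to 1")
  expect_error(pwm("bad", matrix(1, 2, 3)), "4 columns")
  expect_error(pwm("bad", matrix(c(1.2, -0.2, 0, 0), 1)), "\\[0, 1\\]")
})

test_that("core length trims uninformative flanks", {
  flanked <- pwm("f", rbind(matrix(0.25, 1, 4),
                            one_hot_pwm("ACGU")$matrix,
                            matrix(0.25, 1, 4)))
  expect_identical(core_length(flanked), 4L)
  expect_identical(core_length(one_hot_pwm("ACGUA")), 5L)
  expect_identical(core_length(uniform_pwm(6)), 0L)
  # interior uniform columns count once the ends are informative
  gapped <- pwm("g", rbind(one_hot_pwm("A")$matrix, matrix(0.25, 3, 4),
                           one_hot_pwm("U")$matrix))
  expect_identical(core_length(gapped), 5L)
})

test_that("k-mer enumeration is complete and lexicographic", {
  ks <- enumerate_kmers(3, 5)
  expect_identical(length(ks), 64L + 256L + 1024L)
  expect_identical(motif_ids(enumerate_kmers(1, 1)), c("A", "C", "G", "U"))
  two <- motif_ids(enumerate_kmers(2, 2))
  expect_identical(length(two), 16L)
  expect_identical(two[1], "AA")
  expect_identical(two[16], "UU")
  expect_identical(two, sort(two))
  expect_error(enumerate_kmers(3, 2), "kmin")
})

test_that("motif sets enforce homogeneity and unique ids", {
  expect_error(motif_set(list(kmer_motif("AAA"), one_hot_pwm("ACG"))),
               "all PWMs or all k-mers")
  expect_error(motif_set(list(kmer_motif("AAA"), kmer_motif("AAA"))),
               "unique")
  expect_identical(motif_set(list())$mode, "empty")
})

test_that("ATtRACT-style fixture curates to the hand-derived survivor set", {
  recs <- read_attract_motifs(fixture_path("attract_db_synthetic.txt"),
                              fixture_path("attract_pwm_synthetic.txt"))
  expect_length(recs, 10)
  cur <- curate_pwms(recs)
  # one designed failure per stage: mouse record, mutated record,
  # duplicated SELEX description, ambiguous identical matrix pair,
  # short-core record, high-entropy record
  expect_identical(cur$audit$n, c(10L, 9L, 8L, 7L, 5L, 4L, 3L))
  expect_true(all(diff(cur$audit$n) <= 0))
  expect_identical(sort(motif_ids(cur$curated)), c("M003", "M009", "M010"))
})

test_that("curation is idempotent", {
  recs <- read_attract_motifs(fixture_path("attract_db_synthetic.txt"),
                              fixture_path("attract_pwm_synthetic.txt"))
  cur1 <- curate_pwms(recs)
  cur2 <- curate_pwms(cur1$curated$members)
  expect_identical(motif_ids(cur2$curated), motif_ids(cur1$curated))
  expect_identical(cur2$audit$n[1], cur2$audit$n[7])
})

test_that("identical matrices spanning several RBPs are all dropped", {
  shared <- matrix(c(0.7, 0.1, 0.1, 0.1), 4, 4, byrow = TRUE)
  recs <- list(
    pwm("P1", shared, rbp_name = "RBP1", gene_id = "g1",
        species = "Homo_sapiens", experiment = "e1"),
    pwm("P2", shared, rbp_name = "RBP2", gene_id = "g2",
        species = "Homo_sapiens", experiment = "e2"))
  cur <- curate_pwms(recs)
  expect_length(cur$curated$members, 0)
  # same RBP twice: one representative kept
  recs2 <- list(
    pwm("P1", shared, rbp_name = "RBP1", gene_id = "g1",
        species = "Homo_sapiens", experiment = "e1"),
    pwm("P2", shared, rbp_name = "RBP1", gene_id = "g1",
        species = "Homo_sapiens", experiment = "e2"))
  expect_length(curate_pwms(recs2)$curated$members, 1)
})

test_that("unparseable matrix blocks are skipped with a warning", {
  db <- tempfile(fileext = ".txt")
  mx <- tempfile(fileext = ".txt")
  writeLines(paste(c("Matrix_id", "Gene_name", "Gene_id", "Organism",
                     "Mutated", "Experiment_description"),
                   collapse = "\t"), db)
  write(paste(c("B1", "X", "gx", "Homo_sapiens", "no", "e"),
              collapse = "\t"), db, append = TRUE)
  writeLines(c(">B1", "0.25 0.25 0.25", "0.25 0.25 0.25 0.25"), mx)
  w <- capture_warnings(recs <- read_attract_motifs(db, mx))
  expect_match(w, "unparseable|no parseable", all = TRUE)
  expect_length(recs, 0)
})

test_that("curated sets round-trip through the writers", {
  recs <- read_attract_motifs(fixture_path("attract_db_synthetic.txt"),
                              fixture_path("attract_pwm_synthetic.txt"))
  cur <- curate_pwms(recs)$curated
  sf <- tempfile(fileext = ".tsv")
  mf <- tempfile(fileext = ".txt")
  summary <- write_motif_set(cur, sf, mf)
  expect_identical(summary$pwm_id, motif_ids(cur))
  back <- rbpimpact:::read_pwm_matrices(mf)
  expect_identical(names(back), motif_ids(cur))
  for (id in names(back)) {
    expect_equal(back[[id]], unname(cur$members[[id]]$matrix),
                 tolerance = 1e-6)
  }
})
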