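# Shared fixture builders and a per-session cache for expensive
# simulations reused across test files.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) {
    assign(key, force(expr), envir = .cache)
  }
  get(key, envir = .cache)
}

one_hot_pwm <- function(seq, pwm_id = seq, ...) {
  bases <- strsplit(seq, "")[[1]]
  m <- matrix(0, length(bases), 4)
  m[cbind(seq_along(bases), match(bases, c("A", "C", "G", "U")))] <- 1
  pwm(pwm_id, m, ...)
}

uniform_pwm <- function(L, pwm_id = "uniform", ...) {
  pwm(pwm_id, matrix(0.25, L, 4), ...)
}

fixture_path <- function(file) {
  system.file("extdata", file, package = "rbpimpact")
}

# Minimal three-exon gene (one inclusion + one skipping isoform) used by
# the event-selection tests. Exon lengths: 100, `exon_len`, 100 on a
# 1000-nt chromosome starting at position 1.
toy_annotation <- function(exon_len = 60, strand = "+",
                           with_skip = TRUE) {
  e1 <- c(1L, 100L)
  e2 <- c(301L, 300L + exon_len)
  e3 <- c(701L, 800L)
  starts <- c(e1[1], e2[1], e3[1], if (with_skip) c(e1[1], e3[1]))
  ends <- c(e1[2], e2[2], e3[2], if (with_skip) c(e1[2], e3[2]))
  tx <- c(rep("t.incl", 3), if (with_skip) rep("t.skip", 2))
  GenomicRanges::GRanges(
    seqnames = "chr1", ranges = IRanges::IRanges(starts, ends),
    strand = strand, type = "exon", transcript_id = tx, gene_id = "g1")
}

toy_junctions <- function(incl_up = 8, incl_down = 8, skip = 2,
                          exon_len = 60, strand = "+",
                          samples = c("s1", "s2")) {
  ids <- c(junction_id("chr1", 101, 300, strand),
           junction_id("chr1", 301 + exon_len, 700, strand),
           junction_id("chr1", 101, 700, strand))
  counts <- matrix(rep(c(incl_up, incl_down, skip), length(samples)),
                   ncol = length(samples),
                   dimnames = list(NULL, samples))
  data.frame(junction_id = ids, counts, stringsAsFactors = FALSE)
}

pentaU_run <- function() {
  cached("pentaU_sim", simulate_splicing_dataset(
    sim_preset("pentaU_repressor", seed = 20260926)))
}
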