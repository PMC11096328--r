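#' @importFrom stats pnorm dnorm p.adjust t.test rbinom rnorm rpois rmultinom
#'   runif sd var quantile setNames ave
#' @importFrom utils read.table write.table
#' @importFrom methods is as
NULL

RNA_BASES <- c("A", "C", "G", "U")

#' Convert a DNA string to the RNA alphabet
#'
#' All motif matching in this package happens in sense (pre-mRNA) orientation
#' over the RNA alphabet, so genomic sequences are transcribed on read.
#'
#' @param x character vector of DNA or RNA sequences.
#' @return character vector over A, C, G, U.
#' @export
dna_to_rna <- function(x) {
  chartr("Tt", "Uu", toupper(x))
}

#' Reverse-complement an RNA string
#' @param x character vector of RNA sequences.
#' @return reverse complement, RNA alphabet.
#' @export
rna_revcomp <- function(x) {
  out <- chartr("ACGU", "UGCA", toupper(x))
  vapply(strsplit(out, ""), function(s) paste(rev(s), collapse = ""), "")
}

#' Check a sequence is over the RNA alphabet
#' @keywords internal
assert_rna <- function(seq) {
  bad <- grepl("[^ACGU]", seq)
  if (any(bad)) {
    stop("sequence contains characters outside {A,C,G,U}: ",
         substr(seq[bad][1], 1, 40), call. = FALSE)
  }
  invisible(seq)
}

#' Running-mean smoothing with edge shrinkage
#'
#' Averages each position over `[i - halfwidth, i + halfwidth]`, truncating
#' the kernel at the array boundaries so edges are means over fewer points
#' rather than NA.
#'
#' @param x numeric vector.
#' @param halfwidth integer smoothing half-width in positions.
#' @return numeric vector of the same length.
#' @keywords internal
running_mean <- function(x, halfwidth) {
  if (halfwidth <= 0) return(x)
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - halfwidth)
    hi <- min(n, i + halfwidth)
    out[i] <- mean(x[lo:hi])
  }
  out
}

#' Derive a stream-specific RNG seed from a master seed
#'
#' Keeps results below `.Machine$integer.max` so `set.seed()` is safe on
#' 32-bit integers; used to give every stochastic stage its own
#' reproducible stream.
#'
#' @param seed master integer seed.
#' @param stream small integer stream index.
#' @return derived integer seed.
#' @export
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 7919 + stream * 104729) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble per-chromosome coverage into an RleList
#' @param x named list of `Rle` (or numeric) per-chromosome coverage.
#' @return a named `RleList`.
#' @export
as_rle_list <- function(x) {
  x <- lapply(x, function(v) if (is(v, "Rle")) v else S4Vectors::Rle(v))
  do.call(IRanges::RleList, c(x, list(compress = FALSE)))
}
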