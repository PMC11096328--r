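#' Gate samples on RNA-Seq quality metrics
#'
#' A sample passes when its Transcript Integrity Number exceeds 50, the
#' fractions of uniquely mapped and high-quality mapped reads exceed 0.95
#' and 0.85, and rRNA and intergenic read fractions stay below 0.05 and
#' 0.1. Samples with any missing metric are flagged unevaluable and
#' excluded with a warning.
#'
#' @param metrics data.frame with columns `sample_id`, `tin`, `frac_unique`,
#'   `frac_hq`, `frac_rrna`, `frac_intergenic`.
#' @return data.frame with columns `sample_id`, `pass` (logical, NA when
#'   unevaluable) and `reason`.
#' @export
filter_samples_by_qc <- function(metrics) {
  needed <- c("sample_id", "tin", "frac_unique", "frac_hq", "frac_rrna",
              "frac_intergenic")
  missing <- setdiff(needed, colnames(metrics))
  if (length(missing)) {
    stop("QC table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  res <- data.frame(sample_id = metrics$sample_id, pass = NA,
                    reason = "", stringsAsFactors = FALSE)
  for (i in seq_len(nrow(metrics))) {
    m <- metrics[i, ]
    if (anyNA(m[needed[-1]])) {
      res$pass[i] <- NA
      res$reason[i] <- "unevaluable: missing metric"
      next
    }
    fails <- c(
      if (m$tin <= 50) "tin",
      if (m$frac_unique <= 0.95) "frac_unique",
      if (m$frac_hq <= 0.85) "frac_hq",
      if (m$frac_rrna >= 0.05) "frac_rrna",
      if (m$frac_intergenic >= 0.1) "frac_intergenic")
    res$pass[i] <- length(fails) == 0L
    res$reason[i] <- if (length(fails)) paste(fails, collapse = ",") else "ok"
  }
  if (anyNA(res$pass)) {
    warning(sum(is.na(res$pass)), " sample(s) unevaluable (missing metrics)",
            call. = FALSE)
  }
  res
}

#' Cassette-exon inclusion fraction from junction reads
#'
#' Inclusion evidence is the average of the two inclusion junctions,
#' `i = (incl_up + incl_down) / 2`, and the inclusion fraction is
#' `f = i / (i + skip)`. Events with no supporting reads return `NA`.
#'
#' @param incl_up,incl_down,skip non-negative junction read counts
#'   (vectorized).
#' @return inclusion fraction in `[0, 1]`, `NA` where `i + skip == 0`.
#' @export
inclusion_fraction <- function(incl_up, incl_down, skip) {
  if (any(c(incl_up, incl_down, skip) < 0, na.rm = TRUE)) {
    stop("junction counts must be non-negative", call. = FALSE)
  }
  i <- (incl_up + incl_down) / 2
  tot <- i + skip
  ifelse(tot > 0, i / tot, NA_real_)
}

#' Relative poly(A)-site usage within a terminal-exon group
#'
#' `u_p = (count_p + pseudocount) / sum_q (count_q + pseudocount)`. The
#' default pseudocount of 1 keeps every usage strictly positive so
#' `log2(u)` stays finite.
#'
#' @param counts numeric vector of per-site 3'-end read counts for the
#'   sites of one exon (length >= 2).
#' @param pseudocount non-negative pseudocount added to every site.
#' @return usage fractions summing to 1.
#' @export
relative_pas_usage <- function(counts, pseudocount = 1) {
  if (length(counts) < 2L) {
    stop("an exon group needs at least 2 poly(A) sites", call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  x <- counts + pseudocount
  x / sum(x)
}

#' Canonical junction identifier
#'
#' Junctions are keyed by the 1-based genomic coordinates of the first and
#' last intronic base, `chrom:start-end:strand`.
#'
#' @param chrom,start,end,strand junction coordinates.
#' @return character id.
#' @export
junction_id <- function(chrom, start, end, strand) {
  sprintf("%s:%d-%d:%s", chrom, as.integer(start), as.integer(end), strand)
}

#' Select cassette-exon events from an annotation and junction counts
#'
#' An internal exon becomes an event when the annotation contains both an
#' inclusion path (flank -> exon -> flank junctions within one transcript)
#' and a skipping junction (flank -> flank intron in some transcript of the
#' same gene), and the summed junction support across samples reaches
#' `min_support`. Exons shorter than `min_exon_length` are dropped;
#' set `min_exon_length = 0` to keep micro-exons.
#'
#' Flank assignments are in sense orientation: for minus-strand events the
#' sense-upstream flank is the genomically downstream exon.
#'
#' @param annotation a `GRanges` of exons carrying `transcript_id` and
#'   `gene_id` metadata (e.g. `rtracklayer::import(gtf)` subset to
#'   `type == "exon"`), or the path to a GTF file.
#' @param junction_counts data.frame of junction read counts: one row per
#'   junction with a `junction_id` column (see [junction_id()]) and one
#'   numeric column per sample.
#' @param min_support minimum total junction support across samples.
#' @param min_exon_length minimum cassette exon length in nt.
#' @return object of class `"cassette_events"`: list with `events`
#'   (data.frame of coordinates), matrices `incl_up`, `incl_down`, `skip`
#'   and `f` (events x samples), and `samples`.
#' @export
select_cassette_exons <- function(annotation, junction_counts,
                                  min_support = 10, min_exon_length = 50) {
  exons <- load_exon_annotation(annotation)
  samples <- setdiff(colnames(junction_counts), "junction_id")
  if (length(samples) == 0L) stop("no sample columns in junction counts",
                                  call. = FALSE)
  jc <- as.matrix(junction_counts[, samples, drop = FALSE])
  rownames(jc) <- junction_counts$junction_id

  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(exons)),
    start = GenomicRanges::start(exons),
    end = GenomicRanges::end(exons),
    strand = as.character(GenomicRanges::strand(exons)),
    transcript_id = exons$transcript_id,
    gene_id = exons$gene_id, stringsAsFactors = FALSE)
  df <- df[order(df$transcript_id, df$start), ]

  # all annotated introns per gene, for the skip-junction lookup
  introns_by_gene <- new.env(parent = emptyenv())
  for (tx in split(df, df$transcript_id)) {
    n <- nrow(tx)
    if (n < 2L) next
    for (j in seq_len(n - 1L)) {
      key <- paste0(tx$gene_id[1], "\r",
                    junction_id(tx$chrom[j], tx$end[j] + 1L,
                                tx$start[j + 1L] - 1L, tx$strand[j]))
      assign(key, TRUE, envir = introns_by_gene)
    }
  }

  rows <- list()
  for (tx in split(df, df$transcript_id)) {
    n <- nrow(tx)
    if (n < 3L) next
    for (j in 2:(n - 1L)) {
      up_g <- tx[j - 1L, ]   # genomically upstream flank
      ex <- tx[j, ]
      dn_g <- tx[j + 1L, ]
      if (up_g$end >= ex$start || dn_g$start <= ex$end) next  # overlap guard
      j_left <- junction_id(ex$chrom, up_g$end + 1L, ex$start - 1L, ex$strand)
      j_right <- junction_id(ex$chrom, ex$end + 1L, dn_g$start - 1L, ex$strand)
      j_skip <- junction_id(ex$chrom, up_g$end + 1L, dn_g$start - 1L,
                            ex$strand)
      if (!exists(paste0(ex$gene_id, "\r", j_skip), envir = introns_by_gene)) {
        next
      }
      minus <- ex$strand == "-"
      rows[[length(rows) + 1L]] <- data.frame(
        event_id = sprintf("%s:%d-%d:%s", ex$chrom, ex$start, ex$end,
                           ex$strand),
        chrom = ex$chrom, strand = ex$strand,
        exon_start = ex$start, exon_end = ex$end,
        # sense-upstream flank: genomically left on "+", right on "-"
        up_start = if (minus) dn_g$start else up_g$start,
        up_end = if (minus) dn_g$end else up_g$end,
        down_start = if (minus) up_g$start else dn_g$start,
        down_end = if (minus) up_g$end else dn_g$end,
        gene_id = ex$gene_id,
        j_incl_up = if (minus) j_right else j_left,
        j_incl_down = if (minus) j_left else j_right,
        j_skip = j_skip, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(empty_cassette_events(samples))
  }
  ev <- do.call(rbind, rows)
  ev <- ev[!duplicated(ev$event_id), , drop = FALSE]

  lookup <- function(ids) {
    out <- matrix(0, nrow = length(ids), ncol = length(samples),
                  dimnames = list(NULL, samples))
    hit <- ids %in% rownames(jc)
    out[hit, ] <- jc[ids[hit], , drop = FALSE]
    out
  }
  incl_up <- lookup(ev$j_incl_up)
  incl_down <- lookup(ev$j_incl_down)
  skip <- lookup(ev$j_skip)

  support <- rowSums(incl_up) + rowSums(incl_down) + rowSums(skip)
  exlen <- ev$exon_end - ev$exon_start + 1L
  keep <- support >= min_support &
    (min_exon_length <= 0 | exlen >= min_exon_length)
  ev <- ev[keep, , drop = FALSE]
  incl_up <- incl_up[keep, , drop = FALSE]
  incl_down <- incl_down[keep, , drop = FALSE]
  skip <- skip[keep, , drop = FALSE]
  if (nrow(ev) == 0L) return(empty_cassette_events(samples))

  f <- inclusion_fraction(incl_up, incl_down, skip)
  dimnames(f) <- list(ev$event_id, samples)
  rownames(incl_up) <- rownames(incl_down) <- rownames(skip) <- ev$event_id
  rownames(ev) <- NULL
  structure(list(events = ev, incl_up = incl_up, incl_down = incl_down,
                 skip = skip, f = f, samples = samples),
            class = "cassette_events")
}

empty_cassette_events <- function(samples) {
  empty <- matrix(numeric(0), nrow = 0, ncol = length(samples),
                  dimnames = list(NULL, samples))
  structure(list(events = data.frame(), incl_up = empty, incl_down = empty,
                 skip = empty, f = empty, samples = samples),
            class = "cassette_events")
}

#' @export
print.cassette_events <- function(x, ...) {
  cat(sprintf("<cassette_events> %d events x %d samples\n",
              nrow(x$f), ncol(x$f)))
  invisible(x)
}

# Accept a GRanges of exons or a GTF path.
load_exon_annotation <- function(annotation) {
  if (is.character(annotation)) {
    annotation <- rtracklayer::import(annotation, format = "gtf")
  }
  if (!methods::is(annotation, "GRanges")) {
    stop("annotation must be a GRanges or a GTF path", call. = FALSE)
  }
  if ("type" %in% colnames(S4Vectors::mcols(annotation))) {
    annotation <- annotation[annotation$type == "exon"]
  }
  if (!all(c("transcript_id", "gene_id") %in%
           colnames(S4Vectors::mcols(annotation)))) {
    stop("exon annotation needs transcript_id and gene_id", call. = FALSE)
  }
  annotation
}

#' Build a poly(A)-site usage table from site counts
#'
#' Groups tandem poly(A) sites by terminal exon, drops exons with fewer
#' than two sites, and converts per-sample 3'-end counts to relative usage
#' with [relative_pas_usage()].
#'
#' @param sites data.frame with columns `site_id`, `exon_id`, `chrom`,
#'   `strand`, `position` (cleavage site, 1-based) and one numeric count
#'   column per sample.
#' @param pseudocount pseudocount for [relative_pas_usage()].
#' @return object of class `"pas_events"`: list with `sites` (data.frame),
#'   matrices `counts` and `u` (sites x samples), `exon_id` vector aligned
#'   with rows, and `samples`.
#' @export
build_pas_usage <- function(sites, pseudocount = 1) {
  meta_cols <- c("site_id", "exon_id", "chrom", "strand", "position")
  missing <- setdiff(meta_cols, colnames(sites))
  if (length(missing)) {
    stop("site table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  samples <- setdiff(colnames(sites), meta_cols)
  keep_exons <- names(which(table(sites$exon_id) >= 2))
  dropped <- setdiff(unique(sites$exon_id), keep_exons)
  if (length(dropped)) {
    message(length(dropped), " single-site exon group(s) dropped")
  }
  sites <- sites[sites$exon_id %in% keep_exons, , drop = FALSE]
  sites <- sites[order(sites$exon_id, sites$position), , drop = FALSE]
  counts <- as.matrix(sites[, samples, drop = FALSE])
  rownames(counts) <- sites$site_id
  u <- counts
  for (ex in unique(sites$exon_id)) {
    idx <- which(sites$exon_id == ex)
    for (s in seq_along(samples)) {
      u[idx, s] <- relative_pas_usage(counts[idx, s], pseudocount)
    }
  }
  structure(list(sites = sites[, meta_cols], counts = counts, u = u,
                 exon_id = sites$exon_id, samples = samples,
                 pseudocount = pseudocount),
            class = "pas_events")
}

#' @export
print.pas_events <- function(x, ...) {
  cat(sprintf("<pas_events> %d sites in %d exons x %d samples\n",
              nrow(x$u), length(unique(x$exon_id)), ncol(x$u)))
  invisible(x)
}

#' Write cassette-exon events and flanks as BED
#'
#' Coordinates are converted from the internal 1-based inclusive convention
#' to BED's 0-based half-open convention.
#'
#' @param events a `"cassette_events"` object.
#' @param file output path.
#' @return invisibly, the BED data.frame.
#' @export
write_events_bed <- function(events, file) {
  ev <- events$events
  bed <- rbind(
    data.frame(chrom = ev$chrom, start = ev$exon_start - 1L,
               end = ev$exon_end, name = paste0(ev$event_id, "|exon"),
               score = 0L, strand = ev$strand),
    data.frame(chrom = ev$chrom, start = ev$up_start - 1L, end = ev$up_end,
               name = paste0(ev$event_id, "|flank_up"), score = 0L,
               strand = ev$strand),
    data.frame(chrom = ev$chrom, start = ev$down_start - 1L,
               end = ev$down_end, name = paste0(ev$event_id, "|flank_down"),
               score = 0L, strand = ev$strand))
  write.table(bed, file, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(bed)
}

#' Write a per-sample quantification matrix as TSV
#' @param m numeric matrix with row names (events/sites) and sample columns.
#' @param file output path.
#' @param id_col name for the identifier column.
#' @export
write_quant_matrix <- function(m, file, id_col = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
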