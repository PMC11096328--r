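#' Region scheme for sliding windows around processing sites
#'
#' Defines, per site type, how far windows extend upstream and downstream
#' of the site (in sense orientation, nt), the window width and the slide.
#' Defaults cover -300..+100 around 3' splice sites (intronic upstream,
#' exonic downstream), -100..+300 around 5' splice sites and -300..+300
#' around poly(A) sites, tiled by 50-nt windows sliding by 25 nt, plus the
#' central window straddling the site.
#'
#' @param ss3,ss5,pas length-2 numeric vectors `c(upstream_extent,
#'   downstream_extent)` in nt (both positive).
#' @param window_width window width in nt.
#' @param slide slide between consecutive window starts in nt.
#' @param include_central add the `(-width/2, +width/2)` window when it is
#'   not already on the tiling grid.
#' @return object of class `"region_scheme"`.
#' @export
region_scheme <- function(ss3 = c(300, 100), ss5 = c(100, 300),
                          pas = c(300, 300), window_width = 50, slide = 25,
                          include_central = TRUE) {
  if (slide > window_width) stop("slide must not exceed window width",
                                 call. = FALSE)
  for (ext in list(SS3 = ss3, SS5 = ss5, PAS = pas)) {
    if (any(ext < window_width)) {
      stop("region extents must be at least one window wide", call. = FALSE)
    }
  }
  structure(list(extents = list(SS3 = ss3, SS5 = ss5, PAS = pas),
                 window_width = window_width, slide = slide,
                 include_central = include_central),
            class = "region_scheme")
}

#' Generate sliding windows for one site type
#'
#' Windows are half-open offset intervals `[start, end)` in sense
#' orientation with offset 0 at the site anchor (first exonic base for
#' 3'SS, last exonic base for 5'SS, cleavage position for poly(A) sites);
#' negative offsets are upstream. Windows tile
#' `[-upstream_extent, +downstream_extent]` in deterministic
#' upstream-to-downstream order.
#'
#' @param scheme a [region_scheme()].
#' @param site_type one of `"SS3"`, `"SS5"`, `"PAS"`.
#' @return data.frame with columns `site_type`, `start`, `end`,
#'   `window_id`.
#' @export
generate_windows <- function(scheme, site_type = c("SS3", "SS5", "PAS")) {
  site_type <- match.arg(site_type)
  stopifnot(inherits(scheme, "region_scheme"))
  ext <- scheme$extents[[site_type]]
  w <- scheme$window_width
  starts <- seq(-ext[1], ext[2] - w, by = scheme$slide)
  if (scheme$include_central) {
    central <- -w / 2
    if (central >= -ext[1] && central + w <= ext[2] &&
        !(central %in% starts)) {
      starts <- sort(c(starts, central))
    }
  }
  data.frame(site_type = site_type, start = starts, end = starts + w,
             window_id = sprintf("%s_%+d_%+d", site_type, starts,
                                 starts + w),
             stringsAsFactors = FALSE)
}

#' Load a genome as a named DNAStringSet
#'
#' FASTA headers are trimmed at the first whitespace to give chromosome
#' names.
#'
#' @param genome a `Biostrings::DNAStringSet` or the path to a FASTA file.
#' @return a named `DNAStringSet`.
#' @export
load_genome <- function(genome) {
  if (is.character(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  if (!methods::is(genome, "DNAStringSet")) {
    stop("genome must be a DNAStringSet or FASTA path", call. = FALSE)
  }
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' Per-event anchors and offset bounds for one site type
#'
#' Computes, for each event, the genomic anchor position of the requested
#' site and the allowed sense-offset range beyond which windows are masked:
#' exonic-side windows may not extend beyond the cassette exon and
#' intronic-side windows may not extend beyond the flanking intron.
#' Poly(A)-site windows are bounded only by the chromosome.
#'
#' @param events a `"cassette_events"` object (for `"SS3"`/`"SS5"`) or a
#'   `"pas_events"` object (for `"PAS"`).
#' @param site_type one of `"SS3"`, `"SS5"`, `"PAS"`.
#' @return data.frame with columns `event_id`, `chrom`, `strand`, `anchor`
#'   (1-based genomic position of offset 0), `off_lo`, `off_hi` (allowed
#'   half-open offset range, may be infinite).
#' @export
site_table <- function(events, site_type = c("SS3", "SS5", "PAS")) {
  site_type <- match.arg(site_type)
  if (site_type == "PAS") {
    stopifnot(inherits(events, "pas_events"))
    s <- events$sites
    return(data.frame(event_id = s$site_id, chrom = s$chrom,
                      strand = s$strand, anchor = s$position,
                      off_lo = -Inf, off_hi = Inf,
                      stringsAsFactors = FALSE))
  }
  stopifnot(inherits(events, "cassette_events"))
  ev <- events$events
  minus <- ev$strand == "-"
  exon_len <- ev$exon_end - ev$exon_start + 1L
  intron_up <- ifelse(minus, ev$up_start - ev$exon_end - 1L,
                      ev$exon_start - ev$up_end - 1L)
  intron_down <- ifelse(minus, ev$exon_start - ev$down_end - 1L,
                        ev$down_start - ev$exon_end - 1L)
  if (site_type == "SS3") {
    anchor <- ifelse(minus, ev$exon_end, ev$exon_start)
    off_lo <- -intron_up            # most upstream usable offset
    off_hi <- exon_len              # window end may reach exon end
  } else {
    anchor <- ifelse(minus, ev$exon_start, ev$exon_end)
    off_lo <- -(exon_len - 1L)
    off_hi <- intron_down + 1L
  }
  data.frame(event_id = ev$event_id, chrom = ev$chrom, strand = ev$strand,
             anchor = anchor, off_lo = off_lo, off_hi = off_hi,
             stringsAsFactors = FALSE)
}

#' Extract sense-orientation window sequences
#'
#' Maps the offset window `[start, end)` to genomic coordinates (sense
#' offset `o` sits at `anchor + o` on "+" and `anchor - o` on "-"),
#' extracts the genomic slice, reverse-complements minus-strand windows and
#' transcribes to RNA. Windows that cross the event's allowed offset bounds
#' or the chromosome ends are masked (`NA`).
#'
#' @param genome a `DNAStringSet` or FASTA path (see [load_genome()]).
#' @param sites data.frame from [site_table()].
#' @param window one row of [generate_windows()] (or a list with `start`,
#'   `end`).
#' @return character vector of RNA sequences, `NA` for masked windows,
#'   named by `event_id`.
#' @export
extract_window_sequence <- function(genome, sites, window) {
  genome <- load_genome(genome)
  missing_chr <- setdiff(unique(sites$chrom), names(genome))
  if (length(missing_chr)) {
    stop("chromosome(s) missing from FASTA: ",
         paste(missing_chr, collapse = ", "), call. = FALSE)
  }
  a <- window$start
  b <- window$end
  n <- nrow(sites)
  out <- rep(NA_character_, n)
  names(out) <- sites$event_id
  chrlen <- setNames(Biostrings::width(genome), names(genome))
  minus <- sites$strand == "-"
  gstart <- ifelse(minus, sites$anchor - b + 1L, sites$anchor + a)
  gend <- ifelse(minus, sites$anchor - a, sites$anchor + b - 1L)
  ok <- a >= sites$off_lo & b <= sites$off_hi &
    gstart >= 1L & gend <= chrlen[sites$chrom]
  ok[is.na(ok)] <- FALSE
  if (any(ok)) {
    idx <- which(ok)
    seqs <- as.character(Biostrings::subseq(
      genome[sites$chrom[idx]], start = gstart[idx], width = b - a))
    if (any(minus[idx])) {
      seqs[minus[idx]] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(seqs[minus[idx]])))
    }
    out[idx] <- dna_to_rna(seqs)
  }
  out
}

#' Per-start-position PWM binding posteriors
#'
#' At each start position `i` of the sequence, the posterior probability
#' that a binding site of the PWM starts there:
#' `p_i = rho * P_pwm(s_i..s_{i+L-1}) / (rho * P_pwm + (1 - rho) * 0.25^L)`
#' with `P_pwm` the product of the per-position base probabilities and
#' `rho` the prior probability of a site at a given position, against a
#' uniform background.
#'
#' @param seq RNA sequence (character scalar).
#' @param pwm a [pwm()] object.
#' @param prior site prior `rho` in (0, 1).
#' @return numeric vector of posteriors, length `nchar(seq) - L + 1`
#'   (length 0 when the sequence is shorter than the motif).
#' @export
pwm_site_posteriors <- function(seq, pwm, prior = 0.01) {
  assert_rna(seq)
  m <- pwm$matrix
  L <- nrow(m)
  n <- nchar(seq)
  if (n < L) return(numeric(0))
  base_idx <- match(strsplit(seq, "")[[1]], RNA_BASES)
  logm <- log(m)  # -Inf where probability is 0
  nstart <- n - L + 1L
  logp <- numeric(nstart)
  for (j in seq_len(L)) {
    logp <- logp + logm[j, base_idx[seq_len(nstart) + j - 1L]]
  }
  p_pwm <- exp(logp)
  bg <- (1 - prior) * 0.25^L
  (prior * p_pwm) / (prior * p_pwm + bg)
}

#' Motif binding evidence in one sequence
#'
#' k-mer mode counts overlapping exact occurrences; PWM mode returns the
#' sum of per-start-position binding posteriors
#' ([pwm_site_posteriors()]), monotone in the site prior.
#'
#' @param seq RNA sequence.
#' @param motif a [kmer_motif()] or [pwm()].
#' @param prior PWM site prior (ignored in k-mer mode).
#' @return numeric evidence (integer-valued in k-mer mode).
#' @export
count_motif <- function(seq, motif, prior = 0.01) {
  assert_rna(seq)
  if (inherits(motif, "kmer_motif")) {
    k <- motif$k
    n <- nchar(seq)
    if (n < k) return(0)
    starts <- seq_len(n - k + 1L)
    sum(substring(seq, starts, starts + k - 1L) == motif$sequence)
  } else if (inherits(motif, "pwm")) {
    sum(pwm_site_posteriors(seq, motif, prior))
  } else {
    stop("motif must be a kmer_motif or pwm", call. = FALSE)
  }
}

#' Build motif count matrices for a set of windows
#'
#' For every window, extracts the window sequence of every event
#' ([extract_window_sequence()]) and scores every motif of the set in it.
#' Masked windows yield `NA` rows (missing, never zero). k-mer sets are
#' scored with `Biostrings::oligonucleotideFrequency` so that for every
#' unmasked window the counts over all `4^k` k-mers sum to `W - k + 1`.
#'
#' @param genome a `DNAStringSet` or FASTA path.
#' @param sites data.frame from [site_table()].
#' @param windows data.frame from [generate_windows()].
#' @param motifs a [motif_set()].
#' @param prior PWM site prior.
#' @return object of class `"count_matrices"`: list with `windows`
#'   (the input data.frame) and `N`, a list (one entry per window, named by
#'   `window_id`) of events x motifs numeric matrices.
#' @export
build_count_matrix <- function(genome, sites, windows, motifs,
                               prior = 0.01) {
  stopifnot(inherits(motifs, "motif_set"))
  genome <- load_genome(genome)
  ids <- motif_ids(motifs)
  N <- vector("list", nrow(windows))
  names(N) <- windows$window_id
  for (w in seq_len(nrow(windows))) {
    seqs <- extract_window_sequence(genome, sites, windows[w, ])
    mat <- matrix(NA_real_, nrow = length(seqs), ncol = length(ids),
                  dimnames = list(sites$event_id, ids))
    unmasked <- which(!is.na(seqs))
    if (length(unmasked)) {
      if (motifs$mode == "kmer") {
        rss <- Biostrings::RNAStringSet(seqs[unmasked])
        ks <- unique(vapply(motifs$members, `[[`, 1L, "k"))
        for (k in ks) {
          freq <- Biostrings::oligonucleotideFrequency(rss, width = k)
          cols <- intersect(ids, colnames(freq))
          mat[unmasked, cols] <- freq[, cols, drop = FALSE]
        }
      } else {
        for (m in motifs$members) {
          mat[unmasked, m$pwm_id] <- vapply(
            seqs[unmasked], count_motif, 0.0, motif = m, prior = prior,
            USE.NAMES = FALSE)
        }
      }
    }
    N[[w]] <- mat
  }
  structure(list(windows = windows, N = N, mode = motifs$mode,
                 prior = prior),
            class = "count_matrices")
}

#' @export
print.count_matrices <- function(x, ...) {
  cat(sprintf("<count_matrices> %d windows, %d events x %d motifs (%s)\n",
              length(x$N), nrow(x$N[[1]]), ncol(x$N[[1]]), x$mode))
  invisible(x)
}

#' Write count matrices as one TSV per window
#'
#' Files are named `{site}_{start}_{end}.tsv`; a `windows_manifest.tsv`
#' records the grid.
#'
#' @param cm a `"count_matrices"` object.
#' @param dir output directory (created if absent).
#' @return invisibly, the manifest data.frame.
#' @export
write_count_matrices <- function(cm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- cm$windows
  manifest$file <- sprintf("%s_%d_%d.tsv", manifest$site_type,
                           manifest$start, manifest$end)
  for (w in seq_len(nrow(manifest))) {
    write_quant_matrix(cm$N[[w]], file.path(dir, manifest$file[w]),
                       id_col = "event_id")
  }
  write.table(manifest, file.path(dir, "windows_manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
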