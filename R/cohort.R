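#' Classify events by motif binding inside significant regions
#'
#' An event is called bound by a motif when the motif's maximum
#' per-start-position binding posterior within any of its
#' Bonferroni-significant windows reaches the cutoff. With two motifs this
#' yields the four regulation groups `motifA_only`, `motifB_only`,
#' `both`, `neither`.
#'
#' @param binding events x 2 matrix (or data.frame) of per-event maximum
#'   binding posteriors within the significant regions of each motif
#'   (see [max_binding_in_windows()]); column names identify the motifs.
#' @param cutoff binding-probability cutoff in `[0, 1]`.
#' @return data.frame with `event_id`, per-motif probabilities, `group`
#'   and `cutoff`; attribute `"group_sizes"` tabulates the groups.
#' @export
classify_events <- function(binding, cutoff = 0.6) {
  binding <- as.matrix(binding)
  if (ncol(binding) != 2L) {
    stop("binding must have exactly two motif columns", call. = FALSE)
  }
  if (any(binding < 0 | binding > 1, na.rm = TRUE)) {
    stop("binding probabilities must be in [0, 1]", call. = FALSE)
  }
  a <- !is.na(binding[, 1]) & binding[, 1] >= cutoff
  b <- !is.na(binding[, 2]) & binding[, 2] >= cutoff
  motifs <- colnames(binding) %||% c("motifA", "motifB")
  group <- ifelse(a & b, "both",
                  ifelse(a, paste0(motifs[1], "_only"),
                         ifelse(b, paste0(motifs[2], "_only"), "neither")))
  out <- data.frame(event_id = rownames(binding) %||%
                      as.character(seq_len(nrow(binding))),
                    binding, group = group, cutoff = cutoff,
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  attr(out, "group_sizes") <- table(group)
  out
}

#' Maximum binding posterior within a motif's significant windows
#'
#' Scans each event's sequence in the union of the windows where the motif
#' is Bonferroni-significant and records the largest per-start-position
#' posterior ([pwm_site_posteriors()]); k-mer motifs score 1 at exact
#' matches and 0 elsewhere.
#'
#' @param genome `DNAStringSet` or FASTA path.
#' @param sites data.frame from [site_table()] for the relevant site type.
#' @param windows data.frame of significant windows (columns `site_type`,
#'   `start`, `end`), e.g. the distinct significant rows of a
#'   [significance_table()] for the motif.
#' @param motif a [pwm()] or [kmer_motif()].
#' @param prior PWM site prior.
#' @return named numeric vector of per-event maxima (`NA` when every
#'   window is masked for the event).
#' @export
max_binding_in_windows <- function(genome, sites, windows, motif,
                                   prior = 0.01) {
  if (nrow(windows) == 0L) {
    warning("no significant windows; motif never assigned", call. = FALSE)
    return(setNames(rep(NA_real_, nrow(sites)), sites$event_id))
  }
  genome <- load_genome(genome)
  best <- setNames(rep(NA_real_, nrow(sites)), sites$event_id)
  for (w in seq_len(nrow(windows))) {
    seqs <- extract_window_sequence(genome, sites, windows[w, ])
    for (i in which(!is.na(seqs))) {
      p <- if (inherits(motif, "pwm")) {
        ps <- pwm_site_posteriors(seqs[i], motif, prior)
        if (length(ps)) max(ps) else NA_real_
      } else {
        as.numeric(count_motif(seqs[i], motif) > 0)
      }
      if (!is.na(p) && (is.na(best[i]) || p > best[i])) best[i] <- p
    }
  }
  best
}

#' Per-event difference in mean percent-spliced-in between conditions
#'
#' `delta_psi = mean PSI(condition_1) - mean PSI(condition_2)` on the
#' percent scale (inclusion fractions are multiplied by 100). Events
#' missing in every sample of a condition get `NA`.
#'
#' @param f events x samples matrix of inclusion fractions in `[0, 1]`.
#' @param group_labels character/factor of conditions per sample (2
#'   levels); the first level is condition 1.
#' @return named numeric vector of delta-PSI values (percent).
#' @export
delta_psi <- function(f, group_labels) {
  group_labels <- as.factor(group_labels)
  if (nlevels(group_labels) != 2L) stop("need exactly 2 conditions",
                                        call. = FALSE)
  if (any(table(group_labels) < 2)) stop("each condition needs >= 2 samples",
                                         call. = FALSE)
  g1 <- group_labels == levels(group_labels)[1]
  m1 <- rowMeans(f[, g1, drop = FALSE] * 100, na.rm = TRUE)
  m2 <- rowMeans(f[, !g1, drop = FALSE] * 100, na.rm = TRUE)
  out <- m1 - m2
  out[is.nan(m1) | is.nan(m2)] <- NA_real_
  setNames(out, rownames(f))
}

#' Differentially included exons between two conditions
#'
#' Per-event two-sided Welch (unequal-variance) t-test on inclusion
#' fractions, with Benjamini-Hochberg adjustment across events. Events
#' with zero variance in both groups are handled directly: equal means
#' give `p = 1`, different means with zero variance give `p = 0`.
#'
#' @param f events x samples matrix of inclusion fractions.
#' @param group_labels conditions per sample (2 levels, >= 2 samples
#'   each).
#' @return data.frame with `event_id`, `t`, `df`, `p`, `p_adj`,
#'   `delta_psi`.
#' @export
differential_inclusion <- function(f, group_labels) {
  group_labels <- as.factor(group_labels)
  if (nlevels(group_labels) != 2L) stop("need exactly 2 conditions",
                                        call. = FALSE)
  g1 <- group_labels == levels(group_labels)[1]
  res <- t(apply(f, 1, function(row) {
    x <- row[g1]
    y <- row[!g1]
    x <- x[!is.na(x)]
    y <- y[!is.na(y)]
    if (length(x) < 2L || length(y) < 2L) {
      return(c(t = NA_real_, df = NA_real_, p = NA_real_))
    }
    if (var(x) == 0 && var(y) == 0) {
      return(c(t = NA_real_, df = NA_real_,
               p = if (mean(x) == mean(y)) 1 else 0))
    }
    tt <- t.test(x, y, var.equal = FALSE)
    c(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
  }))
  data.frame(event_id = rownames(f) %||% as.character(seq_len(nrow(f))),
             t = res[, "t"], df = res[, "df"], p = res[, "p"],
             p_adj = p.adjust(res[, "p"], method = "BH"),
             delta_psi = delta_psi(f, group_labels),
             row.names = NULL, stringsAsFactors = FALSE)
}
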