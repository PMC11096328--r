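#' Load a coverage track from a bedGraph file
#'
#' Per-chromosome, per-position read coverage with its library size; used
#' as foreground (RBP pulldown) or background (control pulldown) for
#' CLIP-style metaprofiles.
#'
#' @param x a bedGraph path, a `GRanges` with a `score` column, or an
#'   `RleList` of per-chromosome coverage.
#' @param library_size total mapped reads for normalization; defaults to
#'   the total coverage mass of the track.
#' @return object of class `"coverage_track"` with `coverage` (RleList)
#'   and `library_size`.
#' @export
coverage_track <- function(x, library_size = NULL) {
  if (is.character(x)) {
    x <- rtracklayer::import(x, format = "bedGraph")
  }
  if (methods::is(x, "GRanges")) {
    cov <- GenomicRanges::coverage(x, weight = "score")
  } else if (methods::is(x, "RleList")) {
    cov <- x
  } else {
    stop("x must be a bedGraph path, GRanges or RleList", call. = FALSE)
  }
  if (is.null(library_size)) {
    library_size <- sum(vapply(cov, function(r) sum(as.numeric(r)), 0.0))
  }
  if (library_size <= 0) stop("library_size must be positive",
                              call. = FALSE)
  structure(list(coverage = cov, library_size = library_size),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %d chromosome(s), library size %.3g\n",
              length(x$coverage), x$library_size))
  invisible(x)
}

#' Select top-changing target sites and least-changing non-targets
#'
#' @param deltas data.frame with columns `site_id` and `delta` (per-site
#'   change in usage or inclusion, finite).
#' @param direction `"up"` (targets are the largest deltas) or `"down"`
#'   (most negative deltas).
#' @param n_top number of target sites.
#' @param n_least number of least-changing (smallest `|delta|`)
#'   non-target sites.
#' @return list with `targets` and `least_changing` data.frames. Ties are
#'   broken deterministically by site id.
#' @export
select_targets <- function(deltas, direction = c("up", "down"),
                           n_top = 200, n_least = 1000) {
  direction <- match.arg(direction)
  if (!all(is.finite(deltas$delta))) stop("deltas must be finite",
                                          call. = FALSE)
  if (n_top + n_least > nrow(deltas)) {
    stop("need at least ", n_top + n_least, " sites, have ",
         nrow(deltas), call. = FALSE)
  }
  key <- if (direction == "up") -deltas$delta else deltas$delta
  ord <- order(key, deltas$site_id)
  targets <- deltas[ord[seq_len(n_top)], , drop = FALSE]
  rest <- deltas[setdiff(seq_len(nrow(deltas)), ord[seq_len(n_top)]), ,
                 drop = FALSE]
  ord2 <- order(abs(rest$delta), rest$site_id)
  least <- rest[ord2[seq_len(n_least)], , drop = FALSE]
  rownames(targets) <- rownames(least) <- NULL
  list(targets = targets, least_changing = least)
}

# Per-site coverage vectors in sense orientation; rows = sites.
site_coverage_matrix <- function(track, sites, halfwidth) {
  offs <- seq(-halfwidth, halfwidth)
  out <- matrix(NA_real_, nrow = nrow(sites), ncol = length(offs),
                dimnames = list(sites$site_id, offs))
  for (i in seq_len(nrow(sites))) {
    chrom <- sites$chrom[i]
    if (!chrom %in% names(track$coverage)) next
    r <- track$coverage[[chrom]]
    lo <- sites$position[i] - halfwidth
    hi <- sites$position[i] + halfwidth
    if (lo < 1L || hi > length(r)) next  # off-chromosome: site skipped
    v <- as.numeric(r[lo:hi])
    if (sites$strand[i] == "-") v <- rev(v)
    out[i, ] <- v
  }
  out
}

#' Mean foreground/background coverage ratio profile around sites
#'
#' For each site and sense offset, computes the ratio of library-size
#' normalized coverages, `(fg/fg_lib + eps) / (bg/bg_lib + eps)` with a
#' small guard `eps` so zero-background positions stay defined, averages
#' the ratio over sites per offset and applies running-mean smoothing over
#' `+/- smooth` nt. Sites whose window runs off the chromosome are
#' skipped.
#'
#' @param fg,bg [coverage_track()] objects.
#' @param sites data.frame with columns `site_id`, `chrom`, `strand`,
#'   `position`.
#' @param halfwidth profile half-extent in nt.
#' @param smooth smoothing half-width in nt.
#' @param eps ratio guard.
#' @return data.frame with columns `offset` and `ratio` (smoothed mean).
#' @export
ratio_profile <- function(fg, bg, sites, halfwidth = 300, smooth = 5,
                          eps = 1e-9) {
  fgm <- site_coverage_matrix(fg, sites, halfwidth) / fg$library_size
  bgm <- site_coverage_matrix(bg, sites, halfwidth) / bg$library_size
  ok <- rowSums(is.na(fgm)) == 0 & rowSums(is.na(bgm)) == 0
  if (!any(ok)) stop("no usable sites within chromosome bounds",
                     call. = FALSE)
  ratios <- (fgm[ok, , drop = FALSE] + eps) / (bgm[ok, , drop = FALSE] + eps)
  prof <- colMeans(ratios)
  data.frame(offset = seq(-halfwidth, halfwidth),
             ratio = running_mean(prof, smooth))
}

#' Resampled non-target background band
#'
#' Draws `draws` resamples of `draw_size` sites (with replacement) from
#' the least-changing non-targets, computes the smoothed mean ratio
#' profile of each resample, and returns the per-offset mean and standard
#' deviation across resamples — the "mean of means +/- 1 sd" band plotted
#' under target profiles.
#'
#' @param least_changing data.frame of non-target sites (columns as in
#'   [ratio_profile()]).
#' @param fg,bg [coverage_track()] objects.
#' @param draws number of resamples.
#' @param draw_size sites per resample.
#' @param seed RNG seed (resampling is the only stochastic step).
#' @param ... passed to [ratio_profile()].
#' @return data.frame with columns `offset`, `bg_mean`, `bg_sd`.
#' @export
background_band <- function(least_changing, fg, bg, draws = 100,
                            draw_size = 200, seed = 1, ...) {
  if (nrow(least_changing) < 1L) stop("no non-target sites", call. = FALSE)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                     .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  profs <- NULL
  for (d in seq_len(draws)) {
    idx <- sample.int(nrow(least_changing), draw_size, replace = TRUE)
    p <- ratio_profile(fg, bg, least_changing[idx, , drop = FALSE], ...)
    if (is.null(profs)) {
      profs <- matrix(NA_real_, nrow = draws, ncol = nrow(p))
      offsets <- p$offset
    }
    profs[d, ] <- p$ratio
  }
  data.frame(offset = offsets,
             bg_mean = colMeans(profs),
             bg_sd = apply(profs, 2, sd))
}

#' Full metaprofile around target sites
#'
#' Convenience wrapper: the target mean-ratio profile plus the resampled
#' non-target band, aligned on offsets.
#'
#' @param targets,least_changing site data.frames (see [ratio_profile()]).
#' @inheritParams background_band
#' @return data.frame with columns `offset`, `target_mean`, `bg_mean`,
#'   `bg_sd`.
#' @export
meta_profile <- function(targets, least_changing, fg, bg, draws = 100,
                         draw_size = 200, seed = 1, ...) {
  tp <- ratio_profile(fg, bg, targets, ...)
  band <- background_band(least_changing, fg, bg, draws = draws,
                          draw_size = draw_size, seed = seed, ...)
  data.frame(offset = tp$offset, target_mean = tp$ratio,
             bg_mean = band$bg_mean, bg_sd = band$bg_sd)
}
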