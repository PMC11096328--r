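# Linear model of log2 relative poly(A)-site usage.
#
#   log2(u_{p,s}) = Ntilde_p * A_{s} + c_p + c_{s,e} + eps
#
# c_p is the mean log2 relative usage of site p across samples, c_{s,e} the
# mean log2 relative usage of exon e's sites in sample s. Both nuisance
# terms are removed exactly by double centering (across samples per site,
# then across sites within each exon per sample); the motif evidence is
# centered within exons the same way, and the per-sample activity is the
# simple OLS slope of the doubly centered response on the centered
# evidence. For complete site x sample tables this equals the full
# normal-equations OLS fit with explicit indicator covariates (up to the
# inherent common shift of the activities, which centering resolves as
# "relative to the sample mean").

#' Fit per-sample motif activity on poly(A)-site usage
#'
#' @param y sites x samples matrix of `log2` relative usage (finite; build
#'   with [build_pas_usage()] and take `log2(u)`).
#' @param exon_id character vector assigning each row of `y` to its
#'   terminal exon.
#' @param N per-site motif evidence; `NA` marks masked sites, which are
#'   dropped (exon groups left with fewer than 2 sites are dropped too).
#' @param min_sites minimum number of usable sites.
#' @param motif_id,window optional labels carried into the result.
#' @return object of class `c("usage_fit", "activity_fit")` with elements
#'   `A`, `sigma`, `Z` (per-sample), `c_p`, `c_se`, `residuals`,
#'   `n_events` (usable sites), `flag`.
#' @export
fit_usage_activity <- function(y, exon_id, N, min_sites = 10,
                               motif_id = NA_character_, window = NULL) {
  y <- as.matrix(y)
  S <- ncol(y)
  if (S < 2L) stop("need at least 2 samples", call. = FALSE)
  samples <- colnames(y) %||% paste0("s", seq_len(S))
  if (!all(is.finite(y))) stop("y must be finite (use a pseudocount)",
                               call. = FALSE)

  keep <- !is.na(N)
  y <- y[keep, , drop = FALSE]
  exon_id <- exon_id[keep]
  N <- N[keep]
  grp_ok <- names(which(table(exon_id) >= 2))
  keep2 <- exon_id %in% grp_ok
  y <- y[keep2, , drop = FALSE]
  exon_id <- exon_id[keep2]
  N <- N[keep2]
  P <- nrow(y)
  E <- length(unique(exon_id))
  if (P < min_sites) {
    stop("only ", P, " usable sites (need >= ", min_sites, ")",
         call. = FALSE)
  }

  c_p <- rowMeans(y)
  y1 <- y - c_p
  exon_f <- factor(exon_id, levels = unique(exon_id))
  c_se <- apply(y1, 2, function(col) tapply(col, exon_f, mean))
  if (E == 1L) c_se <- matrix(c_se, nrow = 1,
                              dimnames = list(levels(exon_f), samples))
  y2 <- y1 - c_se[as.integer(exon_f), , drop = FALSE]
  Nc <- N - ave(N, exon_f)

  ssn <- sum(Nc^2)
  if (ssn < 1e-12) {
    zero <- setNames(rep(0, S), samples)
    return(structure(list(motif_id = motif_id, window = window, A = zero,
                          sigma = setNames(rep(NA_real_, S), samples),
                          Z = zero, c_p = c_p, c_se = c_se,
                          residuals = y2, loglik = NA_real_, n_events = P,
                          converged = TRUE, flag = "uninformative"),
                     class = c("usage_fit", "activity_fit")))
  }

  A <- colSums(Nc * y2) / ssn
  resid <- y2 - outer(Nc, A)
  rss <- colSums(resid^2)
  df <- P - E - 1L
  if (df <= 0) {
    sigma <- setNames(rep(NA_real_, S), samples)
    Z <- setNames(rep(NA_real_, S), samples)
    flag <- "uninformative"
  } else {
    sigma <- setNames(sqrt(rss / (df * ssn)), samples)
    Z <- setNames(ifelse(sigma > 0, A / sigma, NA_real_), samples)
    flag <- "ok"
  }
  structure(list(motif_id = motif_id, window = window,
                 A = setNames(A, samples), sigma = sigma, Z = Z,
                 c_p = c_p, c_se = c_se, residuals = resid,
                 loglik = NA_real_, n_events = P, converged = TRUE,
                 flag = flag),
            class = c("usage_fit", "activity_fit"))
}

#' Fit usage activities for every motif and window
#'
#' Runs [fit_usage_activity()] for each motif column of each window's
#' count matrix around poly(A) sites.
#'
#' @param pas a `"pas_events"` object.
#' @param cm a `"count_matrices"` object built on
#'   `site_table(pas, "PAS")`.
#' @param ... passed to [fit_usage_activity()].
#' @return list of fits with attribute `"failures"` as in
#'   [fit_inclusion_profiles()].
#' @export
fit_usage_profiles <- function(pas, cm, ...) {
  stopifnot(inherits(pas, "pas_events"), inherits(cm, "count_matrices"))
  y <- log2(pas$u)
  fits <- list()
  fails <- list()
  for (w in seq_len(nrow(cm$windows))) {
    win <- cm$windows[w, ]
    Nmat <- cm$N[[w]][pas$sites$site_id, , drop = FALSE]
    for (m in colnames(Nmat)) {
      fit <- tryCatch(
        fit_usage_activity(y, pas$exon_id, Nmat[, m], motif_id = m,
                           window = win, ...),
        error = function(e) conditionMessage(e))
      if (inherits(fit, "activity_fit")) {
        fits[[length(fits) + 1L]] <- fit
      } else {
        fails[[length(fails) + 1L]] <- data.frame(
          motif_id = m, window_id = win$window_id, reason = fit)
      }
    }
  }
  attr(fits, "failures") <- if (length(fails)) do.call(rbind, fails) else
    data.frame(motif_id = character(), window_id = character(),
               reason = character())
  fits
}
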