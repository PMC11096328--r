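# Penalized binomial logistic model of cassette-exon inclusion.
#
# For inclusion evidence i_{e,s} out of n_{e,s} trials, the inclusion
# probability is Theta_{e,s} = logistic(X_{e,s}) with
#   X_{e,s} = b_s + c_e + Ntilde_e * A_s,
# Ntilde the event-mean-centered motif evidence, b_s a per-sample baseline,
# c_e a per-exon baseline and A_s the per-sample motif activity. The MAP is
# found under Gaussian priors A ~ N(0, tau^2), b, c ~ N(0, 10^2) and the
# identifiability constraints sum_s A_s = 0, sum_e c_e = 0, with fitting
# errors from a Laplace approximation (inverse observed information).

logistic_loglik <- function(i, n, X) {
  # i*X - n*log(1 + exp(X)), overflow-safe
  sum(i * X - n * (pmax(X, 0) + log1p(exp(-abs(X)))))
}

#' Fit per-sample motif activity on exon inclusion
#'
#' Maximizes the penalized binomial log-likelihood of the logistic
#' inclusion model (see Details) by Newton-Raphson with step-halving,
#' deterministic all-zero initialization, and exact sum-to-zero constraints
#' on the activities and the per-exon baselines. Per-sample fitting errors
#' `sigma` come from the diagonal of the inverse observed information at
#' the optimum, and `Z = A / sigma`.
#'
#' @details The model is `i_{e,s} ~ Binomial(n_{e,s}, Theta_{e,s})` with
#' `Theta = logistic(b_s + c_e + Ntilde_e A_s)`. Cells with `n = 0`
#' (no junction support) contribute nothing. Effective totals are capped at
#' `cap` (counts rescaled proportionally) so very deep libraries do not
#' shrink the errors unrealistically. A constant motif-evidence column
#' cannot be separated from the baselines and yields an "uninformative"
#' fit with `A = 0`, `Z = 0`.
#'
#' @param incl events x samples matrix of inclusion evidence
#'   (`(incl_up + incl_down) / 2`; non-integers allowed).
#' @param total events x samples matrix of totals (`incl + skip`), `0`
#'   marking missing cells.
#' @param N per-event motif evidence (length = rows of `incl`); `NA`
#'   marks masked events, which are dropped.
#' @param tau prior standard deviation of the activities.
#' @param sigma_baseline prior standard deviation of `b` and `c`.
#' @param cap maximum effective total per cell.
#' @param min_events minimum number of usable events.
#' @param max_iter,tol Newton iteration cap and convergence threshold on
#'   the largest parameter change.
#' @param motif_id,window optional labels carried into the result.
#' @return object of class `"activity_fit"` with elements `A`, `sigma`,
#'   `Z` (named per-sample vectors), `b`, `c`, `theta`, `X`, `loglik`,
#'   `n_events`, `converged` and `flag` (`"ok"`, `"uninformative"` or
#'   `"nonconverged"`).
#' @export
fit_inclusion_activity <- function(incl, total, N, tau = 1,
                                   sigma_baseline = 10, cap = 100,
                                   min_events = 10, max_iter = 200,
                                   tol = 1e-8, motif_id = NA_character_,
                                   window = NULL) {
  incl <- as.matrix(incl)
  total <- as.matrix(total)
  S <- ncol(incl)
  if (S < 2L) stop("need at least 2 samples", call. = FALSE)
  samples <- colnames(incl) %||% paste0("s", seq_len(S))

  keep <- !is.na(N) & rowSums(total, na.rm = TRUE) > 0
  incl <- incl[keep, , drop = FALSE]
  total <- total[keep, , drop = FALSE]
  N <- N[keep]
  E <- nrow(incl)
  if (E < min_events) {
    stop("only ", E, " usable events (need >= ", min_events, ")",
         call. = FALSE)
  }
  incl[is.na(incl)] <- 0
  total[is.na(total)] <- 0
  over <- total > cap
  if (any(over)) {
    scale <- cap / total[over]
    incl[over] <- incl[over] * scale
    total[over] <- cap
  }

  Nc <- N - mean(N)
  if (max(abs(Nc)) < 1e-12) {
    zero <- setNames(rep(0, S), samples)
    return(structure(list(motif_id = motif_id, window = window,
                          A = zero, sigma = setNames(rep(NA_real_, S),
                                                     samples),
                          Z = zero, b = zero,
                          c = setNames(rep(0, E), rownames(incl)),
                          theta = NULL, X = NULL, loglik = NA_real_,
                          n_events = E, converged = TRUE,
                          flag = "uninformative"),
                     class = "activity_fit"))
  }

  vb <- sigma_baseline^2
  vt <- tau^2
  b <- rep(0, S)
  A <- rep(0, S)
  cc <- rep(0, E)
  alpha <- rep(0, S - 1L)
  gamma <- rep(0, E - 1L)

  pen_ll <- function(b, A, cc) {
    X <- matrix(b, E, S, byrow = TRUE) + cc + outer(Nc, A)
    logistic_loglik(incl, total, X) -
      sum(A^2) / (2 * vt) - sum(b^2) / (2 * vb) - sum(cc^2) / (2 * vb)
  }

  # Sherman-Morrison solve of (diag(h[-E]) + h[E] * 11') x = v for matrix V
  sm_solve <- function(h, V) {
    V <- as.matrix(V)
    linv <- 1 / h[-length(h)]
    hE <- h[length(h)]
    X0 <- V * linv
    denom <- 1 + hE * sum(linv)
    X0 - outer(linv, colSums(X0)) * (hE / denom)
  }

  ll <- pen_ll(b, A, cc)
  converged <- FALSE
  Suu_inv <- NULL
  for (iter in seq_len(max_iter)) {
    X <- matrix(b, E, S, byrow = TRUE) + cc + outer(Nc, A)
    Theta <- 1 / (1 + exp(-X))
    R <- incl - total * Theta
    W <- total * Theta * (1 - Theta)
    W <- pmax(W, 0)

    g_b <- colSums(R) - b / vb
    g_A <- colSums(R * Nc) - A / vt
    g_c <- rowSums(R) - cc / vb
    g_alpha <- g_A[-S] - g_A[S]
    g_gamma <- g_c[-E] - g_c[E]

    wb <- colSums(W) + 1 / vb                  # H_bb diagonal
    wa <- colSums(W * Nc^2) + 1 / vt           # H_AA diagonal
    wba <- colSums(W * Nc)                     # H_bA diagonal
    hc <- rowSums(W) + 1 / vb                  # H_cc diagonal (E)

    # reduced u = (b, alpha) block
    H_aa <- diag(wa[-S], S - 1L) + wa[S]
    H_ba <- rbind(diag(wba[-S], S - 1L), 0)[seq_len(S), , drop = FALSE]
    H_ba[S, ] <- -wba[S]
    H_uu <- rbind(cbind(diag(wb, S), H_ba),
                  cbind(t(H_ba), H_aa))

    WN <- W * Nc
    # H_{u,gamma}: (2S-1) x (E-1)
    H_bg <- t(W[-E, , drop = FALSE]) -
      matrix(W[E, ], S, E - 1L)
    WNd <- t(WN[-E, , drop = FALSE]) - matrix(WN[E, ], S, E - 1L)
    H_ag <- WNd[-S, , drop = FALSE] -
      matrix(WNd[S, ], S - 1L, E - 1L, byrow = TRUE)
    H_ug <- rbind(H_bg, H_ag)

    g_u <- c(g_b, g_alpha)
    Xg <- sm_solve(hc, t(H_ug))                 # (E-1) x (2S-1)
    M <- H_uu - H_ug %*% Xg
    rhs_u <- g_u - H_ug %*% sm_solve(hc, g_gamma)
    du <- solve(M, rhs_u)
    dg <- sm_solve(hc, g_gamma - t(H_ug) %*% du)

    db <- du[seq_len(S)]
    dalpha <- du[S + seq_len(S - 1L)]
    dA <- c(dalpha, -sum(dalpha))
    dcc <- c(dg, -sum(dg))

    step <- 1
    repeat {
      b2 <- b + step * db
      A2 <- A + step * dA
      cc2 <- cc + step * dcc
      ll2 <- pen_ll(b2, A2, cc2)
      if (is.finite(ll2) && ll2 >= ll - 1e-12) break
      step <- step / 2
      if (step < 1e-10) break
    }
    delta <- max(abs(c(step * db, step * dA, step * dcc)))
    b <- b2; A <- A2; cc <- cc2; ll <- ll2
    if (delta < tol) {
      converged <- TRUE
      Suu_inv <- solve(M)
      break
    }
  }
  if (is.null(Suu_inv)) Suu_inv <- NULL

  if (!converged) {
    flag <- "nonconverged"
    sigma <- setNames(rep(NA_real_, S), samples)
    Z <- setNames(rep(NA_real_, S), samples)
  } else {
    flag <- "ok"
    # covariance of A = C Sigma_alpha C' with C the sum-to-zero contrast
    Sig_a <- Suu_inv[S + seq_len(S - 1L), S + seq_len(S - 1L),
                     drop = FALSE]
    Cmat <- rbind(diag(S - 1L), rep(-1, S - 1L))
    covA <- Cmat %*% Sig_a %*% t(Cmat)
    sigma <- setNames(sqrt(pmax(diag(covA), 0)), samples)
    Z <- setNames(ifelse(sigma > 0, A / sigma, NA_real_), samples)
  }

  X <- matrix(b, E, S, byrow = TRUE) + cc + outer(Nc, A)
  structure(list(motif_id = motif_id, window = window,
                 A = setNames(A, samples), sigma = sigma, Z = Z,
                 b = setNames(b, samples),
                 c = setNames(cc, rownames(incl)),
                 theta = 1 / (1 + exp(-X)), X = X, loglik = ll,
                 n_events = E, converged = converged, flag = flag),
            class = "activity_fit")
}

#' @export
print.activity_fit <- function(x, ...) {
  cat(sprintf("<activity_fit> motif=%s, %d events, flag=%s\n",
              x$motif_id, x$n_events, x$flag))
  if (x$flag == "ok") {
    print(round(rbind(A = x$A, sigma = x$sigma, Z = x$Z), 4))
  }
  invisible(x)
}

#' Fit inclusion activities for every motif and window
#'
#' Runs [fit_inclusion_activity()] for each motif column of each window's
#' count matrix. Windows or motifs failing the minimum-event requirement
#' are recorded with flag `"insufficient"` and `NA` statistics.
#'
#' @param events a `"cassette_events"` object.
#' @param cm a `"count_matrices"` object built on the matching
#'   [site_table()].
#' @param ... passed to [fit_inclusion_activity()].
#' @return list of `"activity_fit"` objects (one per motif x window with a
#'   successful fit) with attribute `"failures"`, a data.frame of skipped
#'   combinations.
#' @export
fit_inclusion_profiles <- function(events, cm, ...) {
  stopifnot(inherits(events, "cassette_events"),
            inherits(cm, "count_matrices"))
  incl <- (events$incl_up + events$incl_down) / 2
  total <- incl + events$skip
  fits <- list()
  fails <- list()
  for (w in seq_len(nrow(cm$windows))) {
    win <- cm$windows[w, ]
    Nmat <- cm$N[[w]]
    Nmat <- Nmat[events$events$event_id, , drop = FALSE]
    for (m in colnames(Nmat)) {
      fit <- tryCatch(
        fit_inclusion_activity(incl, total, Nmat[, m], motif_id = m,
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

#' Long-format activity z-score table
#'
#' One row per motif x window x sample. Uninformative or non-converged
#' fits are emitted with `NA` z-scores (never 0), keeping them out of the
#' significance analysis without distorting the background.
#'
#' @param fits list of `"activity_fit"` objects (from either processing
#'   model).
#' @return data.frame with columns `motif_id`, `site_type`,
#'   `window_start`, `window_end`, `sample`, `A`, `sigma`, `Z`, `flag`.
#' @export
activity_zscore_table <- function(fits) {
  rows <- lapply(fits, function(f) {
    S <- length(f$A)
    bad <- f$flag != "ok"
    data.frame(motif_id = f$motif_id,
               site_type = f$window$site_type,
               window_start = f$window$start,
               window_end = f$window$end,
               sample = names(f$A),
               A = if (bad) NA_real_ else unname(f$A),
               sigma = if (bad) NA_real_ else unname(f$sigma),
               Z = if (bad) NA_real_ else unname(f$Z),
               flag = f$flag, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
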