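#' Local cyclicity estimators
#'
#' Score every admissible stride time N for one analysis-window channel.
#' The window holds values `w(nu)` for lags `nu = -K..K` around the window
#' center; each estimator compares the presumed current stride
#' `w(0..N-1)` with the presumed previous stride `w(-N..-1)`:
#'
#' * `score_autocorr` (estimator 1): `S1(N) = (1/N) sum w(nu) w(nu - N)`.
#' * `score_amdf` (estimator 2): inverted average magnitude difference,
#'   `S2(N) = 1 / (eps + (1/N) sum |w(nu) - w(nu - N)|)`.
#' * `score_map` (estimator 3): maximum amplitude pairs,
#'   `S3(N) = max_nu (w(nu) + w(nu - N))`.
#' * `score_dtw` (estimator 4): `S4(N) = 1 / (eps + DTW(w(-N..-1), w(0..N-1)))`
#'   with absolute local cost and Sakoe-Chiba band radius `max(2, N/10)`
#'   (rounded half away from zero).
#'
#' Larger scores mean stronger evidence for period N. `eps = 1e-12`.
#'
#' @param window numeric window vector of odd length `2K + 1`, lags `-K..K`.
#' @param N_range integer candidate periods, all `<= K`.
#' @param zero_lag 1-based index of lag 0 within `window`; defaults to the
#'   middle sample.
#' @param band DTW band radius override; `NULL` uses `max(2, round(N/10))`.
#' @return named numeric vector of raw scores, one per N.
#' @seealso [to_posterior()], [fuse_posteriors()]
#' @export
score_autocorr <- function(window, N_range, zero_lag = NULL)
  score_one_(window, N_range, zero_lag, 1L)

#' @rdname score_autocorr
#' @export
score_amdf <- function(window, N_range, zero_lag = NULL)
  score_one_(window, N_range, zero_lag, 2L)

#' @rdname score_autocorr
#' @export
score_map <- function(window, N_range, zero_lag = NULL)
  score_one_(window, N_range, zero_lag, 3L)

#' @rdname score_autocorr
#' @export
score_dtw <- function(window, N_range, zero_lag = NULL, band = NULL)
  score_one_(window, N_range, zero_lag, 4L,
             dtw_band = if (is.null(band)) -1L else as.integer(band))

score_one_ <- function(window, N_range, zero_lag, est, dtw_band = -1L) {
  N_range <- as.integer(N_range)
  if (length(N_range) < 1L || any(N_range < 1L)) stop("invalid N_range")
  if (is.null(zero_lag)) zero_lag <- (length(window) + 1L) %/% 2L
  lo <- min(N_range); hi <- max(N_range)
  m <- score_window_(as.numeric(window), zero_lag - 1L, lo, hi,
                     est, dtw_band)
  s <- m[N_range - lo + 1L, est]
  names(s) <- N_range
  s
}

#' Banded dynamic time warping cost
#'
#' DTW between two equal-length sequences with absolute local cost,
#' restricted to the Sakoe-Chiba band `|i - j| <= band`. With
#' `band >= length(a)` this is the full (unbanded) dynamic program.
#'
#' @param a,b numeric sequences of equal length.
#' @param band non-negative band radius.
#' @return the accumulated warping cost.
#' @export
dtw_banded <- function(a, b, band) {
  dtw_banded_(as.numeric(a), as.numeric(b), as.integer(band))
}

#' Convert raw cyclicity scores to a posterior curve
#'
#' Scores are shifted so their minimum is zero and normalized to sum to one.
#' This mapping is robust to negative correlation scores and introduces no
#' temperature hyperparameter; a flat score vector maps to the uniform
#' distribution.
#'
#' @param scores named numeric vector of raw scores (names = N support).
#' @param support integer support; defaults to `as.integer(names(scores))`.
#' @return an object of class `posterior_curve` with fields `support` and
#'   `probs` (non-negative, summing to one).
#' @export
to_posterior <- function(scores, support = NULL) {
  if (is.null(support)) support <- as.integer(names(scores))
  if (is.null(support) || anyNA(support))
    stop("scores must be named by their stride-time support")
  keep <- is.finite(scores)
  if (!any(keep)) stop("all scores are non-finite")
  s <- scores
  s[!keep] <- min(scores[keep])
  s <- s - min(s)
  tot <- sum(s)
  probs <- if (tot <= 0) rep(1 / length(s), length(s)) else s / tot
  structure(list(support = support, probs = unname(probs)),
            class = "posterior_curve")
}

#' @export
print.posterior_curve <- function(x, ...) {
  i <- posterior_argmax_idx(x$probs)
  cat(sprintf("posterior_curve over N in [%d, %d]: argmax N = %d (p = %.3f)\n",
              min(x$support), max(x$support), x$support[i], x$probs[i]))
  invisible(x)
}

# floor applied inside products so one dissenting estimator cannot zero a
# candidate period
PROB_FLOOR <- 1e-12

#' Fuse posterior curves by normalized product
#'
#' Element-wise product of the curves' probabilities (computed in log space
#' with a floor of 1e-12 per element), renormalized to sum to one. The
#' product is the joint Bayesian estimate across estimators and/or channels.
#'
#' @param curves list of `posterior_curve` objects sharing one support.
#' @return a fused `posterior_curve`.
#' @export
fuse_posteriors <- function(curves) {
  if (inherits(curves, "posterior_curve")) curves <- list(curves)
  if (length(curves) < 1L) stop("no posterior curves to fuse")
  support <- curves[[1]]$support
  lp <- rep(0, length(support))
  for (cv in curves) {
    if (!identical(cv$support, support))
      stop("posterior curves must share the same support")
    lp <- lp + log(pmax(cv$probs, PROB_FLOOR))
  }
  p <- exp(lp - max(lp))
  structure(list(support = support, probs = p / sum(p)),
            class = "posterior_curve")
}

# Index of the maximum with ties (relative tolerance 1e-9) broken toward the
# smallest N, biasing against period doubling.
posterior_argmax_idx <- function(probs, tol = 1e-9) {
  m <- max(probs)
  which(probs >= m - tol * max(m, .Machine$double.xmin))[1]
}

#' Most likely stride time and its confidence
#'
#' @param curve a `posterior_curve`.
#' @return list with `N` (argmax of the posterior; ties break toward the
#'   smallest admissible N) and `confidence` (the posterior maximum).
#' @export
posterior_peak <- function(curve) {
  i <- posterior_argmax_idx(curve$probs)
  list(N = curve$support[i], confidence = curve$probs[i])
}
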