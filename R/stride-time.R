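#' Sweep analysis windows over a signal and estimate stride times
#'
#' Slides analysis windows of half-width `Nmax` with step `eta` over the
#' signal. For each window center and each channel the selected cyclicity
#' estimators are scored over the admissible stride times and fused into a
#' per-component posterior, giving the component stride time `N[k, s]` and
#' confidence `v[k, s]` (the posterior maximum). The product over all
#' channels and estimators gives the globally fused stride time `N_fused[k]`.
#'
#' Window centers start at the first fully valid position `Nmax` (0-based)
#' and stop at `l - 1 - Nmax`; no partial windows are evaluated. A signal
#' shorter than one full window yields an empty series with a warning.
#'
#' @param signal a [compound_signal()].
#' @param config a [cyclicity_config()].
#' @return an object of class `stride_time_series`: list with `centers`
#'   (0-based sample indices), matrices `N` and `v` (windows x channels),
#'   `N_fused`, `support`, `channel_labels`, `config` and `ell`.
#' @export
sweep_windows <- function(signal, config) {
  stopifnot(inherits(signal, "compound_signal"),
            inherits(config, "cyclicity_config"))
  ell <- signal_length(signal)
  K <- config$Nmax
  L <- n_channels(signal)
  support <- config$Nmin:config$Nmax
  empty <- structure(
    list(centers = integer(0),
         N = matrix(integer(0), 0, L,
                    dimnames = list(NULL, signal$channel_labels)),
         v = matrix(numeric(0), 0, L,
                    dimnames = list(NULL, signal$channel_labels)),
         N_fused = integer(0), support = support,
         channel_labels = signal$channel_labels,
         config = config, ell = ell),
    class = "stride_time_series")
  if (ell < 2L * K + 1L) {
    warning("signal shorter than one analysis window (", 2L * K + 1L,
            " samples); returning empty series")
    return(empty)
  }
  centers <- seq.int(K, ell - 1L - K, by = config$eta)
  nk <- length(centers)
  Nmat <- matrix(NA_integer_, nk, L,
                 dimnames = list(NULL, signal$channel_labels))
  vmat <- matrix(NA_real_, nk, L,
                 dimnames = list(NULL, signal$channel_labels))
  Nfused <- integer(nk)
  est <- config$estimators
  X <- signal$samples
  nsup <- length(support)

  for (k in seq_len(nk)) {
    c1 <- centers[k] + 1L  # R index of the center sample
    rows <- (c1 - K):(c1 + K)
    lp_global <- rep(0, nsup)
    for (s in seq_len(L)) {
      sc <- score_window_(X[rows, s], K, config$Nmin, config$Nmax, est, -1L)
      lp_comp <- rep(0, nsup)
      for (e in est) {
        p <- to_posterior(sc[, e], support = support)$probs
        lp_comp <- lp_comp + log(pmax(p, PROB_FLOOR))
      }
      pc <- exp(lp_comp - max(lp_comp))
      pc <- pc / sum(pc)
      i <- posterior_argmax_idx(pc)
      Nmat[k, s] <- support[i]
      vmat[k, s] <- pc[i]
      lp_global <- lp_global + lp_comp
    }
    Nfused[k] <- support[posterior_argmax_idx(exp(lp_global - max(lp_global)))]
  }
  structure(
    list(centers = centers, N = Nmat, v = vmat, N_fused = Nfused,
         support = support, channel_labels = signal$channel_labels,
         config = config, ell = ell),
    class = "stride_time_series")
}

#' @export
print.stride_time_series <- function(x, ...) {
  cat(sprintf("stride_time_series: %d windows x %d channels (eta = %d)\n",
              length(x$centers), ncol(x$N), x$config$eta))
  if (length(x$centers))
    cat(sprintf("  fused stride time: median %d samples, range [%d, %d]\n",
                as.integer(stats::median(x$N_fused)), min(x$N_fused),
                max(x$N_fused)))
  invisible(x)
}

#' @export
as.data.frame.stride_time_series <- function(x, ...) {
  df <- data.frame(center = x$centers)
  for (s in colnames(x$N)) {
    df[[paste0("N_", s)]] <- x$N[, s]
    df[[paste0("v_", s)]] <- x$v[, s]
  }
  df$N_fused <- x$N_fused
  df
}

#' Global stride-time track g(n)
#'
#' Nearest-neighbour interpolation of the fused stride times onto every
#' sample position: `g(n)` equals the fused stride time of the window center
#' nearest to n (equidistant ties resolve to the earlier center; positions
#' beyond the first/last center clamp to the edge value).
#'
#' @param series a non-empty `stride_time_series`.
#' @param ell signal length; defaults to the length recorded in the series.
#' @return an object of class `stride_time_track`: list with `g` (integer
#'   vector of length `ell`, indexed by 0-based sample position + 1) and
#'   `centers`.
#' @export
build_track <- function(series, ell = series$ell) {
  if (length(series$centers) == 0L)
    stop("cannot build a track from an empty stride-time series")
  cs <- series$centers
  n <- 0:(ell - 1L)
  if (length(cs) == 1L) {
    idx <- rep(1L, ell)
  } else {
    bounds <- (cs[-length(cs)] + cs[-1]) / 2
    # a sample exactly on a midpoint goes to the earlier center
    idx <- findInterval(n, bounds, left.open = TRUE) + 1L
  }
  structure(list(g = series$N_fused[idx], centers = cs, ell = ell),
            class = "stride_time_track")
}

#' Evaluate the stride-time track at sample positions
#'
#' @param track a `stride_time_track`.
#' @param n 0-based sample positions in `[0, ell)`.
#' @return fused stride times `g(n)` in samples.
#' @export
track_at <- function(track, n) {
  n <- as.integer(n)
  if (any(n < 0L | n >= track$ell)) stop("position outside [0, ell)")
  track$g[n + 1L]
}

#' @export
print.stride_time_track <- function(x, ...) {
  cat(sprintf("stride_time_track over %d samples (%d centers)\n",
              x$ell, length(x$centers)))
  invisible(x)
}
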