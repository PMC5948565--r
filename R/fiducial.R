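FIDUCIAL_KINDS <- c("M", "m", "z", "h", "s")

#' Fiducial-point specification
#'
#' Pairs a sensor channel with a fiducial kind. Kinds follow the field's
#' compact notation: `"M"` local maxima (e.g. heel-strike spikes in
#' acceleration), `"m"` local minima, `"z"` zero-crossings (toe-off on the
#' gyroscope z axis), `"h"` abrupt negative change (heel strike on the
#' accelerometer y axis), `"s"` zero-energy plateau midpoint (mid-stance on
#' the gyroscope energy channel).
#'
#' @param channel channel label.
#' @param kind one of `"M"`, `"m"`, `"z"`, `"h"`, `"s"`.
#' @return an object of class `fiducial_spec` with a `label` of the form
#'   `"channel[kind]"`.
#' @export
fiducial_spec <- function(channel, kind) {
  if (!kind %in% FIDUCIAL_KINDS)
    stop("kind must be one of ", paste(FIDUCIAL_KINDS, collapse = ", "))
  structure(list(channel = channel, kind = kind,
                 label = paste0(channel, "[", kind, "]")),
            class = "fiducial_spec")
}

#' @export
print.fiducial_spec <- function(x, ...) {
  cat("fiducial_spec:", x$label, "\n")
  invisible(x)
}

# channel-group tokens of the compact notation -> channel label stems
.spec_tokens <- list(
  Acc = function(axes) paste0("acc_", axes),
  Gyr = function(axes) paste0("gyr_", axes),
  Mag = function(axes) paste0("mag_", axes),
  AM  = function(axes) "am",
  GE  = function(axes) "ge")

#' Parse a compact estimator/component/fiducial specification
#'
#' Parses strings of the form `estimators-Components-axes-[kinds]`, e.g.
#' `"1234-AccGyr-A-[M|m]"` (all four estimators, accelerometer and gyroscope
#' on all axes, maxima and minima as fiducial points), `"Gyr-z-[m]"`, or
#' `"GE-x-[s]"`. The leading estimator digits are optional. Axes `"A"` means
#' all three spatial axes. Each channel-kind pair becomes its own output
#' component, so `"AccGyr-A-[M|m]"` yields twelve components.
#'
#' @param text specification string.
#' @param channel_labels optional available channel labels; parsed channels
#'   are restricted to this set (an error is raised if none survive).
#' @return list with `estimators` (integer vector, `NULL` when absent) and
#'   `specs` (list of [fiducial_spec()]).
#' @export
parse_fiducial_spec <- function(text, channel_labels = NULL) {
  parts <- strsplit(text, "-", fixed = TRUE)[[1]]
  if (length(parts) < 2L) stop("cannot parse fiducial spec: ", text)
  estimators <- NULL
  if (grepl("^[1-4]+$", parts[1])) {
    estimators <- sort(unique(as.integer(strsplit(parts[1], "")[[1]])))
    parts <- parts[-1]
  }
  kinds_part <- parts[length(parts)]
  if (!grepl("^\\[.*\\]$", kinds_part))
    stop("fiducial kinds must be bracketed, e.g. [M|m]: ", text)
  kinds <- strsplit(gsub("^\\[|\\]$", "", kinds_part), "|", fixed = TRUE)[[1]]
  bad <- setdiff(kinds, FIDUCIAL_KINDS)
  if (length(bad)) stop("unknown fiducial kind(s): ", paste(bad, collapse = ","))
  comp_part <- parts[1]
  axes <- if (length(parts) >= 3L) parts[2] else "A"
  axes <- if (identical(axes, "A")) c("x", "y", "z")
          else strsplit(axes, "")[[1]]
  if (!all(axes %in% c("x", "y", "z"))) stop("invalid axes in spec: ", text)

  channels <- character(0)
  rest <- comp_part
  while (nchar(rest) > 0L) {
    hit <- NULL
    for (tok in names(.spec_tokens)) {
      if (startsWith(rest, tok)) { hit <- tok; break }
    }
    if (is.null(hit)) stop("unknown component token in spec: ", rest)
    channels <- c(channels, .spec_tokens[[hit]](axes))
    rest <- substring(rest, nchar(hit) + 1L)
  }
  if (!is.null(channel_labels)) {
    channels <- intersect(channels, channel_labels)
    if (length(channels) == 0L)
      stop("no channels of spec '", text, "' present in the signal")
  }
  specs <- list()
  for (ch in channels)
    for (kd in kinds)
      specs[[length(specs) + 1L]] <- fiducial_spec(ch, kd)
  list(estimators = estimators, specs = specs)
}

#' Locate a fiducial point inside one analysis window
#'
#' Given the estimated stride time N for a window, searches the lags
#' `m = 0..N` (the window's right half) for the fiducial point of the
#' requested kind, pairing each lag with its counterpart one stride earlier:
#'
#' * `"M"`: `argmax_m (w(m) + w(m - N))` -- paired local maxima.
#' * `"m"`: `argmin_m (w(m) + w(m - N))` -- paired local minima.
#' * `"z"`: `argmin_m |w(m) - w(m - N)|` restricted to lags where the signal
#'   changes sign within +/- 2 samples; empty when no sign change exists.
#' * `"h"`: `argmin_m (w(m) - w(m - 1))` -- the most abrupt negative change.
#' * `"s"`: midpoint of the longest run with `|w| < hr` within `[0, N]`
#'   (ties toward the earlier run/midpoint); empty when no such run exists.
#'
#' @param window numeric window vector (lags `-K..K`).
#' @param N estimated stride time in samples (`N <= K`).
#' @param kind fiducial kind or a [fiducial_spec()].
#' @param hr noise threshold for the zero-energy kind, in channel units.
#' @param zero_lag 1-based index of lag 0; defaults to the middle sample.
#' @return the selected lag `m*` in `0..N`, or `integer(0)` when no
#'   candidate exists.
#' @export
apply_fiducial <- function(window, N, kind, hr = 0, zero_lag = NULL) {
  if (inherits(kind, "fiducial_spec")) kind <- kind$kind
  if (!kind %in% FIDUCIAL_KINDS) stop("unknown fiducial kind: ", kind)
  N <- as.integer(N)
  if (is.null(zero_lag)) zero_lag <- (length(window) + 1L) %/% 2L
  if (zero_lag - N < 1L || zero_lag + N > length(window))
    stop("window too short for N = ", N)
  m <- 0:N
  a <- window[zero_lag + m]        # w(m)
  b <- window[zero_lag + m - N]    # w(m - N)
  if (kind == "M") return(m[which.max(a + b)])
  if (kind == "m") return(m[which.min(a + b)])
  if (kind == "h") {
    d <- window[zero_lag + m] - window[zero_lag + m - 1L]
    return(m[which.min(d)])
  }
  if (kind == "z") {
    # sign changes between adjacent samples of the whole window
    w <- window
    cross <- w[-length(w)] * w[-1] <= 0 &
      !(w[-length(w)] == 0 & w[-1] == 0)
    near <- vapply(m, function(mi) {
      j <- (zero_lag + mi - 2L):(zero_lag + mi + 1L)
      j <- j[j >= 1L & j <= length(cross)]
      any(cross[j])
    }, logical(1))
    if (!any(near)) return(integer(0))
    cand <- m[near]
    return(cand[which.min(abs(a - b)[near])])
  }
  # kind "s": zero-energy plateau midpoint
  low <- abs(a) < hr
  if (!any(low)) return(integer(0))
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]  # ties -> earlier run
  lo <- starts[best]; hi <- ends[best]
  m[lo + (hi - lo) %/% 2L]                   # ties -> earlier midpoint
}

#' Collect replicated stride-position candidates
#'
#' Applies the fiducial function of every component (channel + kind) to
#' every analysis window, emitting one candidate per window: global position
#' `t = nk + m*`, stride time `d = N[k, s]` and confidence `v = v[k, s]`.
#' Because the window step is much smaller than the window, each true
#' fiducial point receives many replicated votes.
#'
#' @param signal the [compound_signal()] the series was computed from.
#' @param series a [sweep_windows()] result.
#' @param specs a [fiducial_spec()], a list of them, or a compact
#'   specification string (see [parse_fiducial_spec()]).
#' @param hr noise threshold forwarded to the zero-energy fiducial kind;
#'   defaults to the config's `hr` (maximum across channels if named).
#' @return named list of data frames (`t`, `d`, `v`), one per component
#'   label, each carrying the channel label as attribute `"channel"`.
#' @export
collect_candidates <- function(signal, series, specs, hr = NULL) {
  if (is.character(specs))
    specs <- parse_fiducial_spec(specs, signal$channel_labels)$specs
  if (inherits(specs, "fiducial_spec")) specs <- list(specs)
  cfg <- series$config
  if (is.null(hr)) hr <- if (length(cfg$hr)) max(cfg$hr) else 0
  K <- cfg$Nmax
  out <- list()
  for (sp in specs) {
    s <- match(sp$channel, series$channel_labels)
    if (is.na(s)) stop("unknown channel in fiducial spec: ", sp$channel)
    x <- signal$samples[, s]
    nk <- length(series$centers)
    tt <- integer(nk); dd <- integer(nk); vv <- numeric(nk)
    keep <- logical(nk)
    for (k in seq_len(nk)) {
      ck <- series$centers[k]
      w <- x[(ck + 1L - K):(ck + 1L + K)]
      N <- series$N[k, s]
      mstar <- apply_fiducial(w, N, sp$kind, hr = hr_for(hr, sp$channel))
      if (length(mstar)) {
        keep[k] <- TRUE
        tt[k] <- ck + mstar
        dd[k] <- N
        vv[k] <- series$v[k, s]
      }
    }
    df <- data.frame(t = tt[keep], d = dd[keep], v = vv[keep])
    attr(df, "channel") <- sp$channel
    out[[sp$label]] <- df
  }
  out
}

# resolve a possibly channel-named hr threshold for one channel
hr_for <- function(hr, channel) {
  if (is.null(names(hr))) return(hr[1])
  if (channel %in% names(hr)) unname(hr[channel]) else 0
}

#' Consolidate replicated candidates into unique stride triplets
#'
#' Groups candidates voting for the same fiducial point (positions within
#' `merge_tol` samples of the majority position), then per group takes the
#' modal stride time (ties toward the smaller d), the mean confidence, and
#' keeps only groups backed by enough replicated votes:
#' `count / l_exp > h` with `l_exp = min(d, t) / eta` (windows whose right
#' half can contain the point; `lexp_rule = "printed"` uses `t / eta`).
#'
#' @param candidates data frame with columns `t`, `d`, `v` (one component).
#' @param eta analysis-window step in samples.
#' @param h replication ratio threshold in (0, 1].
#' @param merge_tol grouping tolerance in samples.
#' @param lexp_rule `"min"` or `"printed"`, see above.
#' @return data frame of stride triplets (`t`, `d`, `v`, `count`, `lexp`)
#'   sorted by position; the `"channel"` attribute is carried over.
#' @export
consolidate <- function(candidates, eta, h = 0.75, merge_tol = 1,
                        lexp_rule = c("min", "printed")) {
  lexp_rule <- match.arg(lexp_rule)
  empty <- data.frame(t = integer(0), d = integer(0), v = numeric(0),
                      count = integer(0), lexp = numeric(0))
  attr(empty, "channel") <- attr(candidates, "channel")
  if (nrow(candidates) == 0L) return(empty)
  tt <- candidates$t; dd <- candidates$d; vv <- candidates$v
  res_t <- integer(0); res_d <- integer(0); res_v <- numeric(0)
  res_n <- integer(0); res_e <- numeric(0)
  alive <- rep(TRUE, length(tt))
  while (any(alive)) {
    tab <- table(tt[alive])
    pos <- as.integer(names(tab))
    t_mode <- pos[tab == max(tab)][1]          # ties -> smallest position
    grp <- alive & abs(tt - t_mode) <= merge_tol
    dg <- dd[grp]
    dt <- table(dg)
    d_hat <- as.integer(names(dt)[dt == max(dt)][1])  # ties -> smaller d
    lexp <- switch(lexp_rule,
                   min = min(d_hat, t_mode) / eta,
                   printed = t_mode / eta)
    lexp <- max(lexp, 1)
    res_t <- c(res_t, t_mode); res_d <- c(res_d, d_hat)
    res_v <- c(res_v, mean(vv[grp]))
    res_n <- c(res_n, sum(grp)); res_e <- c(res_e, lexp)
    alive <- alive & !grp
  }
  keep <- res_n / res_e > h
  o <- order(res_t[keep])
  out <- data.frame(t = res_t[keep][o], d = res_d[keep][o],
                    v = res_v[keep][o], count = res_n[keep][o],
                    lexp = res_e[keep][o])
  attr(out, "channel") <- attr(candidates, "channel")
  out
}

#' Remove unreliable and incorrect strides
#'
#' Applies the two fixed robustness thresholds: triplets with confidence
#' below `hv` are dropped, and triplets whose stride interval
#' `[t - d, t]` shows a channel dynamic range (max - min) below `hr` are
#' dropped as silence/sensor noise. The local (per-stride) dynamic range is
#' used so silent stretches are rejected even inside otherwise active
#' recordings. Output is always a subset of the input, order preserved.
#'
#' @param triplets consolidated stride triplets (data frame `t`, `d`, `v`).
#' @param hv stride confidence threshold in \[0, 1\].
#' @param hr noise variability threshold in channel units (scalar or named
#'   by channel).
#' @param signal the [compound_signal()], required when `hr > 0`.
#' @param channel channel label the triplets belong to; defaults to the
#'   `"channel"` attribute.
#' @return the filtered triplets.
#' @export
filter_unreliable <- function(triplets, hv = 0, hr = 0, signal = NULL,
                              channel = attr(triplets, "channel")) {
  keep <- triplets$v >= hv
  hr_ch <- hr_for(hr, channel)
  if (hr_ch > 0) {
    if (is.null(signal)) stop("hr filtering requires the signal")
    x <- channel_values(signal, channel)
    for (i in which(keep)) {
      lo <- max(0L, triplets$t[i] - triplets$d[i])
      seg <- x[(lo + 1L):(triplets$t[i] + 1L)]
      if (diff(range(seg)) < hr_ch) keep[i] <- FALSE
    }
  }
  out <- triplets[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "channel") <- channel
  out
}
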