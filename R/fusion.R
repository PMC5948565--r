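#' Select the reference component
#'
#' The reference is the component whose observed inter-stride intervals
#' agree best with the globally tracked stride time:
#' `argmin_s mean_i |g(t_i,s) - (t_i,s - t_{i-1},s)|` over strides `i > 1`.
#' A manual choice can be forced instead, e.g. the gyroscope z axis for
#' shoe-mounted sensors.
#'
#' @param triplets_by_comp named list of stride-triplet data frames.
#' @param track a [build_track()] result.
#' @param manual optional component label to force.
#' @return the reference component label, with the per-component scores as
#'   attribute `"scores"`.
#' @export
select_reference <- function(triplets_by_comp, track, manual = NULL) {
  if (!is.null(manual)) {
    if (!manual %in% names(triplets_by_comp))
      stop("manual reference '", manual, "' is not a component")
    return(manual)
  }
  scores <- vapply(triplets_by_comp, function(tr) {
    if (nrow(tr) < 2L) return(NA_real_)
    dt <- diff(tr$t)
    mean(abs(track_at(track, tr$t[-1]) - dt))
  }, numeric(1))
  if (all(is.na(scores)))
    stop("no component has at least two strides; cannot select a reference")
  ref <- names(scores)[which.min(scores)]
  attr(ref, "scores") <- scores
  ref
}

#' Build a sparse confidence vector from stride triplets
#'
#' Length-`ell` vector that is zero except at stride positions, where it
#' carries the stride confidence (a weighted Kronecker-delta train);
#' coinciding strides sum.
#'
#' @param triplets data frame (`t`, `v`).
#' @param ell signal length in samples.
#' @return numeric vector of length `ell` (index = 0-based position + 1).
#' @export
build_sparse <- function(triplets, ell) {
  r <- numeric(ell)
  if (nrow(triplets)) {
    if (any(triplets$t < 0L | triplets$t >= ell))
      stop("stride position outside [0, ell)")
    for (i in seq_len(nrow(triplets)))
      r[triplets$t[i] + 1L] <- r[triplets$t[i] + 1L] + triplets$v[i]
  }
  r
}

# narrow symmetric triangular smear so near-coincident spikes still
# correlate; both trains get the same kernel, which preserves the argmax lag
smear_train <- function(x, half_width = 2L) {
  if (length(x) <= 2L * half_width) return(x)
  k <- 1 - abs(seq(-half_width, half_width)) / (half_width + 1)
  y <- as.numeric(stats::filter(x, k / sum(k), sides = 2))
  y[is.na(y)] <- 0
  y
}

# argmax of the normalized cross-correlation sum(ref(n) * other(n + tau))
# over tau in [-max_lag, max_lag]; ties -> smallest |tau|, then negative.
# Positive lag means `other` runs late relative to `ref`. The spike trains
# are smeared by a narrow triangle so detections scattered by a sample or
# two still vote for their common lag.
cross_corr_lag <- function(ref, other, max_lag) {
  n <- length(ref)
  stopifnot(length(other) == n)
  taus <- (-max_lag):max_lag
  if (sum(ref^2) == 0 || sum(other^2) == 0) {
    warning("zero-energy sparse vector; using lag 0")
    return(structure(0L, ncc = NA_real_))
  }
  ref <- smear_train(ref)
  other <- smear_train(other)
  norm <- sqrt(sum(ref^2) * sum(other^2))
  cc <- vapply(taus, function(tau) {
    if (tau >= 0) sum(ref[seq_len(n - tau)] * other[seq_len(n - tau) + tau])
    else sum(ref[(1 - tau):n] * other[seq_len(n + tau)])
  }, numeric(1)) / norm
  m <- max(cc)
  cand <- taus[cc >= m - 1e-12 * max(1, abs(m))]
  cand <- cand[order(abs(cand), cand)]
  structure(as.integer(cand[1]), ncc = m)
}

# result(n) = x(n - k): spikes move k samples later for k > 0
shift_vector <- function(x, k) {
  n <- length(x)
  out <- numeric(n)
  if (k >= 0) out[(1 + k):n] <- x[seq_len(n - k)]
  else out[seq_len(n + k)] <- x[(1 - k):n]
  out
}

#' Align a component's sparse stride train to the reference
#'
#' Estimates the fixed fiducial lag between a component and the reference by
#' normalized cross-correlation of their sparse confidence vectors, with the
#' lag constrained to the physiological range `[-Nmax, Nmax]`. The returned
#' lag is the estimated delay of `other` relative to `ref` (positive =
#' `other` fires later); the aligned vector has that delay removed. When
#' gait sequences are supplied, one lag is estimated per reference sequence
#' span (carrying posture may change between sequences) and each of the
#' component's strides is shifted by the lag of its nearest span.
#'
#' @param ref,other sparse confidence vectors of equal length.
#' @param Nmax maximum admissible lag in samples.
#' @param ref_sequences optional `gait_sequences` of the reference
#'   component (or data frame with `onset`, `send`).
#' @return list with `lags` (one per sequence, or one global lag) and
#'   `aligned` (the shifted vector).
#' @export
align_sparse <- function(ref, other, Nmax, ref_sequences = NULL) {
  ell <- length(ref)
  if (is.null(ref_sequences) || length(ref_sequences) == 0L) {
    lag <- cross_corr_lag(ref, other, Nmax)
    return(list(lags = as.integer(lag), aligned = shift_vector(other, -lag)))
  }
  spans <- if (is.data.frame(ref_sequences)) ref_sequences
           else as.data.frame(ref_sequences)
  nseq <- nrow(spans)
  # global lag as the fallback for spans too sparse to correlate reliably
  global_lag <- if (sum(ref != 0) && sum(other != 0))
    cross_corr_lag(ref, other, Nmax) else 0L
  lags <- integer(nseq)
  for (j in seq_len(nseq)) {
    lo <- max(0L, spans$onset[j] - Nmax)
    hi <- min(ell - 1L, spans$send[j] + Nmax)
    idx <- (lo + 1L):(hi + 1L)
    if (sum(ref[idx] != 0) < 3L || sum(other[idx] != 0) < 2L) {
      lags[j] <- global_lag
    } else {
      lags[j] <- cross_corr_lag(ref[idx], other[idx], Nmax)
    }
  }
  aligned <- numeric(ell)
  nz <- which(other != 0)
  for (p in nz) {
    p0 <- p - 1L
    dist <- pmax(spans$onset - p0, p0 - spans$send, 0L)
    j <- which.min(dist)
    q <- p - lags[j]
    if (q >= 1L && q <= ell) aligned[q] <- aligned[q] + other[p]
  }
  list(lags = lags, aligned = aligned)
}

# valley of a Gaussian KDE over peak heights: the minimum-density point
# between the two largest modes; -Inf (keep everything) when the height
# distribution is unimodal or degenerate
kde_valley <- function(heights) {
  if (length(heights) < 3L || stats::sd(heights) == 0) return(-Inf)
  d <- tryCatch(stats::density(heights, bw = "nrd0"),
                error = function(e) NULL)
  if (is.null(d)) return(-Inf)
  y <- d$y
  ip <- which(diff(sign(diff(y))) < 0) + 1L  # interior local maxima
  if (length(ip) < 2L) return(-Inf)
  top <- ip[order(y[ip], decreasing = TRUE)][1:2]
  lo <- min(top); hi <- max(top)
  seg <- lo:hi
  vi <- seg[which.min(y[seg])]
  # a genuine two-class split needs a valley clearly below both modes;
  # indistinct ripples within one cluster of heights do not separate classes
  if (y[vi] > 0.75 * min(y[top])) return(-Inf)
  d$x[vi]
}

#' Fuse aligned stride trains and enhance stride positions
#'
#' Stacks the aligned sparse confidence vectors into a compound sparse
#' matrix, takes the marginal (column-sum) projection, and smooths it with a
#' unit-area symmetric triangular window (length `fusion_window`, by default
#' the shortest admissible stride time `Nmin`, odd-ified) so that overlaying
#' confidence votes reinforce while isolated outliers stay low. A window as
#' long as `Nmax` would span neighbouring strides and interpolate the spike
#' train into a near-constant trace, so the support is kept below the
#' shortest stride. Local maxima of the smoothed trace are candidate stride positions;
#' their heights form a two-class problem thresholded at the valley of a
#' Gaussian kernel density estimate (Silverman bandwidth; a unimodal height
#' distribution keeps every peak). Final strides are the surviving peaks
#' with stride time `d_i = t_{i+1} - t_i` (the inter-peak interval; set
#' `d_rule = "printed"` for the `t_{i+1}^max - t_i^min` variant) and
#' sharpness confidence `v_i = ((y_i - y_left_min) + (y_i - y_right_min))/2`.
#' Intervals outside `[Nmin, Nmax]` (sequence boundaries, gaps) are reported
#' as `NA` rather than as stride times.
#'
#' Sequences from all components are merged best-first (ascending mean
#' absolute error, i.e. descending reliability); overlapping spans are
#' unioned until the covered temporal span stabilizes.
#'
#' @param aligned list (or matrix rows) of aligned sparse vectors.
#' @param config a [cyclicity_config()].
#' @param comp_sequences optional named list of scored `gait_sequences`
#'   per component, used for the merged sequence output.
#' @param d_rule `"interval"` (default) or `"printed"`.
#' @return list of class `stride_fusion`: `strides` (data frame `t`, `d`,
#'   `v`, `sequence`), `sequences` (merged data frame), `trace` (smoothed
#'   y(n)), `threshold`, `peaks`.
#' @export
fuse_and_enhance <- function(aligned, config, comp_sequences = NULL,
                             d_rule = c("interval", "printed")) {
  d_rule <- match.arg(d_rule)
  if (is.matrix(aligned)) aligned <- asplit(aligned, 1)
  if (length(aligned) < 1L) stop("need at least one aligned vector")
  ell <- length(aligned[[1]])
  ytilde <- Reduce(`+`, aligned)

  Lw <- if (!is.null(config$fusion_window)) config$fusion_window
        else config$Nmin
  if (Lw %% 2L == 0L) Lw <- Lw + 1L  # symmetric center
  half <- (Lw - 1L) / 2
  tri <- 1 - abs(seq(-half, half)) / (half + 1)
  tri <- tri / sum(tri)
  y <- stats::filter(ytilde, tri, method = "convolution", sides = 2)
  y <- as.numeric(y); y[is.na(y)] <- 0

  # interior local maxima of the smoothed trace (plateaus -> first sample)
  pk <- which(y[2:(ell - 1)] > y[1:(ell - 2)] &
                y[2:(ell - 1)] >= y[3:ell] &
                y[2:(ell - 1)] > 0) + 1L
  merged <- merge_component_sequences(comp_sequences)
  if (length(pk) == 0L) {
    warning("no peaks in the fused confidence trace; empty result")
    return(structure(list(
      strides = data.frame(t = integer(0), d = integer(0), v = numeric(0),
                           sequence = integer(0)),
      sequences = merged, trace = y, threshold = NA_real_,
      peaks = integer(0)), class = "stride_fusion"))
  }
  heights <- y[pk]
  thr <- kde_valley(heights)
  keep <- heights > thr
  pk <- pk[keep]; heights <- heights[keep]

  # adjacent minima around each kept peak
  np <- length(pk)
  vmin_l <- numeric(np); vmin_r <- numeric(np)
  bounds <- c(1L, pk, ell)
  for (i in seq_len(np)) {
    vmin_l[i] <- min(y[bounds[i]:pk[i]])
    vmin_r[i] <- min(y[pk[i]:bounds[i + 2L]])
  }
  vi <- ((heights - vmin_l) + (heights - vmin_r)) / 2

  ti <- pk - 1L  # back to 0-based positions
  di <- rep(NA_integer_, np)
  if (np > 1L) {
    gap_next <- diff(ti)
    if (d_rule == "interval") {
      di[-np] <- gap_next
    } else {
      # printed variant: next maximum minus this stride's left minimum
      tmin <- vapply(seq_len(np), function(i)
        (bounds[i]:pk[i])[which.min(y[bounds[i]:pk[i]])] - 1L, integer(1))
      di[-np] <- ti[-1] - tmin[-np]
    }
    bad <- !is.na(di) & (di < config$Nmin | di > config$Nmax)
    if (any(bad)) {
      message(sum(bad), " inter-peak interval(s) outside [Nmin, Nmax] ",
              "reported as NA stride times")
      di[bad] <- NA_integer_
    }
  }
  seq_id <- assign_to_sequences(ti, merged)
  structure(list(
    strides = data.frame(t = ti, d = di, v = vi, sequence = seq_id),
    sequences = merged, trace = y, threshold = thr, peaks = pk),
    class = "stride_fusion")
}

# merge scored sequences from all components best-first (ascending MAE);
# overlapping spans are unioned, keeping the best reliability
merge_component_sequences <- function(comp_sequences) {
  empty <- data.frame(sequence = integer(0), onset = integer(0),
                      send = integer(0), reliability = numeric(0))
  if (is.null(comp_sequences) || length(comp_sequences) == 0L) return(empty)
  rows <- do.call(rbind, lapply(names(comp_sequences), function(nm) {
    df <- as.data.frame(comp_sequences[[nm]])
    if (nrow(df)) df$component <- nm
    df
  }))
  if (is.null(rows) || nrow(rows) == 0L) return(empty)
  rows <- rows[order(rows$reliability), , drop = FALSE]
  spans <- list()
  for (i in seq_len(nrow(rows))) {
    on <- rows$onset[i]; se <- rows$send[i]; rel <- rows$reliability[i]
    hit <- which(vapply(spans, function(sp)
      on <= sp$send && se >= sp$onset, logical(1)))
    if (length(hit)) {
      all_on <- c(on, vapply(spans[hit], `[[`, numeric(1), "onset"))
      all_se <- c(se, vapply(spans[hit], `[[`, numeric(1), "send"))
      all_rel <- c(rel, vapply(spans[hit], `[[`, numeric(1), "reliability"))
      spans[hit] <- NULL
      spans[[length(spans) + 1L]] <- list(onset = min(all_on),
                                          send = max(all_se),
                                          reliability = min(all_rel))
    } else {
      spans[[length(spans) + 1L]] <- list(onset = on, send = se,
                                          reliability = rel)
    }
  }
  ord <- order(vapply(spans, `[[`, numeric(1), "onset"))
  spans <- spans[ord]
  data.frame(sequence = seq_along(spans),
             onset = vapply(spans, `[[`, numeric(1), "onset"),
             send = vapply(spans, `[[`, numeric(1), "send"),
             reliability = vapply(spans, `[[`, numeric(1), "reliability"))
}

# nearest merged sequence id for each stride position (0 distance inside)
assign_to_sequences <- function(ti, merged) {
  if (nrow(merged) == 0L) return(rep(NA_integer_, length(ti)))
  vapply(ti, function(p) {
    dist <- pmax(merged$onset - p, p - merged$send, 0)
    merged$sequence[which.min(dist)]
  }, numeric(1))
}

#' @export
print.stride_fusion <- function(x, ...) {
  cat(sprintf("stride_fusion: %d final stride(s), %d merged sequence(s)\n",
              nrow(x$strides), nrow(x$sequences)))
  if (is.finite(x$threshold))
    cat(sprintf("  KDE peak-height threshold: %.4g\n", x$threshold))
  invisible(x)
}
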