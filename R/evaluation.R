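#' Sample-level gait sequence coverage
#'
#' Labels every sample of the recording as inside/outside a gait sequence
#' for both prediction and ground truth and reports the four-class
#' confusion counts with the standard rates. Intervals are 0-based and
#' inclusive on both ends.
#'
#' @param pred,truth data frames with columns `onset` and `send` (sample
#'   indices), or `gait_sequences` objects.
#' @param ell recording length in samples.
#' @return list with `tp`, `tn`, `fp`, `fn`, `sensitivity`, `specificity`,
#'   `precision`, `recall`, `fall_out` (the FP/(FP+TN) variant) and
#'   `f_score`.
#' @export
sequence_coverage <- function(pred, truth, ell) {
  lab <- function(x) {
    if (inherits(x, "gait_sequences")) x <- as.data.frame(x)
    v <- logical(ell)
    for (i in seq_len(nrow(x))) {
      lo <- max(0L, as.integer(x$onset[i]))
      hi <- min(ell - 1L, as.integer(x$send[i]))
      if (hi >= lo) v[(lo + 1L):(hi + 1L)] <- TRUE
    }
    v
  }
  p <- lab(pred); g <- lab(truth)
  tp <- sum(p & g); tn <- sum(!p & !g)
  fp <- sum(p & !g); fn <- sum(!p & g)
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
    2 * prec * rec / (prec + rec) else NA_real_
  list(tp = tp, tn = tn, fp = fp, fn = fn,
       sensitivity = rec,
       specificity = if (fp + tn > 0) tn / (fp + tn) else NA_real_,
       precision = prec, recall = rec,
       fall_out = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
       f_score = f)
}

#' Match detected stride instants against ground-truth borders
#'
#' A detected stride is a true positive when it falls within `tol_s`
#' (default 100 ms) of a labelled stride border, the closest detection
#' winning per border; every other detection (inside or outside labelled
#' regions) is a false positive, and unmatched borders are false negatives.
#'
#' @param pred detected stride positions (samples, sorted).
#' @param truth labelled stride borders (samples, sorted).
#' @param fsamp sampling frequency in Hz.
#' @param tol_s matching tolerance in seconds.
#' @return list with counts `tp`, `fp`, `fn`, rates `precision`, `recall`,
#'   `f_score`, and `pairs` (matrix of matched pred/truth indices).
#' @export
match_strides <- function(pred, truth, fsamp, tol_s = 0.1) {
  tol <- tol_s * fsamp
  used <- logical(length(pred))
  pairs <- matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("pred", "truth")))
  for (j in seq_along(truth)) {
    if (!length(pred)) break
    dist <- abs(pred - truth[j])
    dist[used] <- Inf
    i <- which.min(dist)
    if (is.finite(dist[i]) && dist[i] <= tol) {
      used[i] <- TRUE
      pairs <- rbind(pairs, c(i, j))
    }
  }
  tp <- nrow(pairs)
  fp <- length(pred) - tp
  fn <- length(truth) - tp
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
    2 * prec * rec / (prec + rec) else NA_real_
  list(tp = tp, fp = fp, fn = fn, precision = prec, recall = rec,
       f_score = f, pairs = pairs)
}

# nearest-rank 95th percentile
p95_nearest_rank <- function(x) {
  if (!length(x)) return(NA_real_)
  sort(x)[ceiling(0.95 * length(x))]
}

#' Stride timing accuracy, bias and agreement
#'
#' Compares matched stride times (and optionally positions) against ground
#' truth: absolute-error statistics, least-squares regression of detected
#' on reference stride times, Bland-Altman agreement (mean difference,
#' reproducibility coefficient `RPC = 1.96 * SD` of the differences,
#' relative RPC and coefficient of variation, both relative to the mean of
#' the pairwise averages), and positioning bias (reference-to-detected
#' fiducial delays `t_i - t_i_ref`).
#'
#' @param pred_d,truth_d paired stride times (samples); pairs with `NA` are
#'   dropped.
#' @param pred_t,truth_t optional paired stride positions for the bias
#'   block.
#' @return list with `n`, `ae` (mean/median/sd/p95), `regression`
#'   (`r_squared`, `sse`, slope/intercept), `bland_altman` (`mean_diff`,
#'   `rpc`, `rpc_relative`, `cv`), and `bias` (mean/sd/median of delays).
#'   Agreement entries are `NA` with fewer than two pairs.
#' @export
timing_accuracy <- function(pred_d, truth_d, pred_t = NULL, truth_t = NULL) {
  keep <- !(is.na(pred_d) | is.na(truth_d))
  pd <- as.numeric(pred_d[keep]); td <- as.numeric(truth_d[keep])
  n <- length(pd)
  ae <- abs(pd - td)
  ae_stats <- list(mean = if (n) mean(ae) else NA_real_,
                   median = if (n) stats::median(ae) else NA_real_,
                   sd = if (n > 1) stats::sd(ae) else NA_real_,
                   p95 = p95_nearest_rank(ae))
  reg <- list(r_squared = NA_real_, sse = NA_real_,
              slope = NA_real_, intercept = NA_real_)
  ba <- list(mean_diff = NA_real_, rpc = NA_real_,
             rpc_relative = NA_real_, cv = NA_real_)
  if (n >= 2) {
    if (all(pd == td)) {
      reg <- list(r_squared = 1, sse = 0, slope = 1, intercept = 0)
    } else if (stats::var(td) > 0) {
      fit <- stats::lm(pd ~ td)
      reg <- list(r_squared = summary(fit)$r.squared,
                  sse = sum(fit$residuals^2),
                  slope = unname(stats::coef(fit)[2]),
                  intercept = unname(stats::coef(fit)[1]))
    }
    diffs <- td - pd
    avgs <- (td + pd) / 2
    rpc <- 1.96 * stats::sd(diffs)
    ba <- list(mean_diff = mean(diffs), rpc = rpc,
               rpc_relative = if (mean(avgs) != 0) rpc / mean(avgs)
                              else NA_real_,
               cv = if (mean(avgs) != 0) stats::sd(diffs) / mean(avgs)
                    else NA_real_)
  }
  bias <- list(mean = NA_real_, sd = NA_real_, median = NA_real_)
  if (!is.null(pred_t) && !is.null(truth_t)) {
    kk <- !(is.na(pred_t) | is.na(truth_t))
    delays <- as.numeric(pred_t[kk]) - as.numeric(truth_t[kk])
    if (length(delays))
      bias <- list(mean = mean(delays),
                   sd = if (length(delays) > 1) stats::sd(delays)
                        else NA_real_,
                   median = stats::median(delays))
  }
  list(n = n, ae = ae_stats, regression = reg, bland_altman = ba,
       bias = bias)
}

#' Precision/recall sweep over the stride confidence threshold
#'
#' Re-filters the detected strides at every grid value of the confidence
#' threshold and records stride-matching precision and recall against the
#' ground-truth borders.
#'
#' @param strides data frame with `t` (positions, samples) and `v`
#'   (confidences).
#' @param truth ground-truth stride borders (samples).
#' @param fsamp sampling frequency in Hz.
#' @param grid threshold grid; default 0 to 1 in steps of 0.01.
#' @param tol_s matching tolerance in seconds.
#' @return data frame (`hv`, `precision`, `recall`, `f_score`).
#' @export
threshold_sweep <- function(strides, truth, fsamp,
                            grid = seq(0, 1, by = 0.01), tol_s = 0.1) {
  res <- lapply(grid, function(hv) {
    kept <- strides$t[strides$v >= hv]
    m <- match_strides(kept, truth, fsamp, tol_s)
    c(precision = m$precision, recall = m$recall, f = m$f_score)
  })
  res <- do.call(rbind, res)
  data.frame(hv = grid, precision = res[, "precision"],
             recall = res[, "recall"], f_score = res[, "f"])
}

#' Select the stride confidence threshold from sweep curves
#'
#' Per trial, the optimal threshold is the grid point where precision and
#' recall intersect (minimum |precision - recall|, ties toward the smaller
#' threshold). The final threshold is the mean of the per-trial optima; its
#' standard deviation indicates the stability of the recognition system.
#'
#' @param sweeps list of [threshold_sweep()] data frames (one per trial).
#' @return list with `hv` (mean optimal threshold), `sd`, and `per_trial`.
#' @export
select_threshold <- function(sweeps) {
  if (is.data.frame(sweeps)) sweeps <- list(sweeps)
  per <- vapply(sweeps, function(sw) {
    gap <- abs(sw$precision - sw$recall)
    gap[!is.finite(gap)] <- Inf
    if (all(!is.finite(gap)) ||
        (length(unique(gap[is.finite(gap)])) == 1L &&
         sum(is.finite(gap)) == length(gap))) {
      warning("degenerate precision/recall curves; using grid midpoint")
      return(sw$hv[ceiling(length(sw$hv) / 2)])
    }
    sw$hv[which.min(gap)]
  }, numeric(1))
  list(hv = mean(per),
       sd = if (length(per) > 1) stats::sd(per) else 0,
       per_trial = per)
}
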