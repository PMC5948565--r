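#' Configuration for local cyclicity estimation
#'
#' Derives the admissible stride-time band in samples from the expected
#' stride-frequency band and holds the tunable parameters of the pipeline.
#' With the default 0.5--3 Hz band the longest admissible stride time is
#' `Nmax = round(fsamp / fmin)` samples (2 s) and the shortest is
#' `Nmin = max(2, round(fsamp / fmax))` samples (1/3 s).
#'
#' @param fsamp sampling frequency in Hz.
#' @param fmin,fmax minimum and maximum expected stride frequency in Hz;
#'   physiological defaults 0.5 and 3 Hz.
#' @param eta analysis-window step in samples; defaults to about 100 ms
#'   (`round(0.1 * fsamp)`), roughly 30% of the shortest admissible stride.
#' @param estimators integer subset of 1:4 selecting local cyclicity
#'   estimators: 1 autocorrelation, 2 inverted average magnitude difference,
#'   3 maximum amplitude pairs, 4 banded dynamic time warping.
#' @param hv stride confidence threshold in \[0, 1\]; triplets with mean
#'   posterior confidence below it are discarded. 0.11 is the value the
#'   threshold-selection protocol converges to on real smartphone data.
#' @param hr noise variability threshold in channel units (scalar, or named
#'   by channel label); a stride interval whose channel dynamic range falls
#'   below `hr` is treated as silence. 0 disables the gate.
#' @param h replication ratio in (0, 1]; a consolidated stride is kept only
#'   when the number of windows voting for it exceeds `h` times the expected
#'   vote count.
#' @param merge_tol position tolerance in samples when grouping replicated
#'   fiducial votes; noise scatters detections over a few samples, and a
#'   1-sample merge is the minimal correction.
#' @param lexp_rule how the expected vote count is computed:
#'   `"min"` uses `min(d, t)/eta` (windows whose right half can contain the
#'   fiducial); `"printed"` uses `t/eta`, which grows with absolute time and
#'   is retained only for comparison.
#' @param fusion_window length in samples of the triangular smoothing
#'   window used when fusing aligned stride trains; defaults to `Nmin`, the
#'   shortest admissible stride time, so replication scatter of a few
#'   samples merges into one peak while every admissible stride spacing
#'   stays resolvable (a window reaching the neighbouring stride would
#'   interpolate the spike train into a flat trace).
#' @param fiducial_spec optional compact fiducial specification string, e.g.
#'   `"1234-AccGyr-A-[M|m]"`; see [parse_fiducial_spec()].
#' @return an object of class `cyclicity_config`.
#' @examples
#' cyclicity_config(fsamp = 25)
#' @export
cyclicity_config <- function(fsamp, fmin = 0.5, fmax = 3, eta = NULL,
                             estimators = 1:4, hv = 0.11, hr = 0,
                             h = 0.75, merge_tol = 1,
                             lexp_rule = c("min", "printed"),
                             fusion_window = NULL,
                             fiducial_spec = NULL) {
  if (fsamp <= 0) stop("fsamp must be positive")
  if (!(fmin > 0 && fmin < fmax)) stop("need 0 < fmin < fmax")
  Nmin <- max(2L, as.integer(round(fsamp / fmax)))
  Nmax <- as.integer(round(fsamp / fmin))
  if (Nmin >= Nmax) stop("degenerate stride-time band: Nmin >= Nmax")
  if (is.null(eta)) eta <- max(1L, as.integer(round(0.1 * fsamp)))
  eta <- as.integer(eta)
  if (eta < 1L || eta > Nmin)
    stop("eta must satisfy 1 <= eta <= Nmin (= ", Nmin, ")")
  estimators <- sort(unique(as.integer(estimators)))
  if (length(estimators) < 1L || any(!estimators %in% 1:4))
    stop("estimators must be a non-empty subset of 1:4")
  if (hv < 0 || hv > 1) stop("hv must lie in [0, 1]")
  if (any(hr < 0)) stop("hr must be non-negative")
  if (h <= 0 || h > 1) stop("h must lie in (0, 1]")
  lexp_rule <- match.arg(lexp_rule)
  if (is.null(fusion_window)) fusion_window <- Nmin
  fusion_window <- as.integer(fusion_window)
  if (fusion_window < 3L) stop("fusion_window must be >= 3 samples")
  structure(
    list(fsamp = fsamp, fmin = fmin, fmax = fmax,
         Nmin = Nmin, Nmax = Nmax, eta = eta,
         estimators = estimators, hv = hv, hr = hr, h = h,
         merge_tol = merge_tol, lexp_rule = lexp_rule,
         fusion_window = fusion_window,
         fiducial_spec = fiducial_spec),
    class = "cyclicity_config"
  )
}

#' @export
print.cyclicity_config <- function(x, ...) {
  cat(sprintf(
    "cyclicity_config: fsamp %g Hz, band %.2g-%.2g Hz -> N in [%d, %d] samples\n",
    x$fsamp, x$fmin, x$fmax, x$Nmin, x$Nmax))
  cat(sprintf("  eta %d samples (%.0f ms), estimators {%s}\n",
              x$eta, 1000 * x$eta / x$fsamp,
              paste(x$estimators, collapse = ",")))
  cat(sprintf("  hv %.3g, hr %s, h %.3g, merge_tol %d, lexp_rule %s\n",
              x$hv, paste(format(x$hr), collapse = "/"), x$h,
              as.integer(x$merge_tol), x$lexp_rule))
  if (!is.null(x$fiducial_spec))
    cat("  fiducial_spec:", x$fiducial_spec, "\n")
  invisible(x)
}

#' Read a cyclicity configuration from a key-value text file
#'
#' The file is a flat YAML mapping whose keys mirror the arguments of
#' [cyclicity_config()] (requires the `yaml` package).
#'
#' @param path file path.
#' @param fsamp sampling frequency, used when the file does not set one.
#' @return a `cyclicity_config`.
#' @export
read_config <- function(path, fsamp = NULL) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading config files requires the 'yaml' package")
  raw <- yaml::yaml.load_file(path)
  if (is.null(raw$fsamp)) raw$fsamp <- fsamp
  if (is.null(raw$fsamp)) stop("config must provide fsamp")
  keep <- intersect(names(raw), names(formals(cyclicity_config)))
  do.call(cyclicity_config, raw[keep])
}
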