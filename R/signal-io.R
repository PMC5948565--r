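#' Read a raw sensor table
#'
#' Reads a delimited text table with one time column plus one numeric column
#' per sensor channel, as exported by phone logging apps. Timestamps may be
#' non-equidistant; the time unit (seconds or milliseconds) is auto-detected
#' from the median spacing unless forced.
#'
#' @param path file path to a comma- or tab-separated table with a header.
#' @param channel_map optional named character vector renaming file columns
#'   to channel labels (`c(file_col = "label")`); unmapped channel columns
#'   are kept under their file names.
#' @param time_unit `"auto"` (median spacing > 1 means milliseconds),
#'   `"s"` or `"ms"`.
#' @param sep field separator; auto-detected from the header when `NULL`.
#' @return an object of class `sensor_series`: list with `time` (seconds,
#'   monotone increasing), `values` (matrix), `channel_labels`, `time_unit`.
#' @export
read_sensor_table <- function(path, channel_map = NULL,
                              time_unit = c("auto", "s", "ms"), sep = NULL) {
  time_unit <- match.arg(time_unit)
  header <- readLines(path, n = 1L)
  if (is.null(sep)) sep <- if (grepl("\t", header)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(tab) < 2L) stop("table must contain a time column and >= 1 channel")

  tnames <- c("t", "time", "timestamp")
  tcol <- which(tolower(names(tab)) %in% tnames)[1]
  if (is.na(tcol))
    stop("no time column found (expected one of: ",
         paste(tnames, collapse = ", "), ")")

  for (j in seq_along(tab)) {
    v <- suppressWarnings(as.numeric(tab[[j]]))
    bad <- which(is.na(v) & !is.na(tab[[j]]))
    if (length(bad))
      stop(sprintf("non-numeric cell at row %d, column '%s'",
                   bad[1], names(tab)[j]))
    tab[[j]] <- v
  }

  tt <- tab[[tcol]]
  if (anyNA(tt)) stop("missing timestamps at row ", which(is.na(tt))[1])
  dt <- diff(tt)
  if (any(dt <= 0)) {
    row <- which(dt <= 0)[1] + 1L
    stop(sprintf("timestamps not strictly increasing at row %d", row))
  }

  detected <- if (time_unit == "auto") {
    if (length(dt) && stats::median(dt) > 1) "ms" else "s"
  } else time_unit
  if (detected == "ms") tt <- tt / 1000

  vals <- as.matrix(tab[, -tcol, drop = FALSE])
  labels <- colnames(vals)
  if (!is.null(channel_map)) {
    hit <- match(labels, names(channel_map))
    labels[!is.na(hit)] <- channel_map[hit[!is.na(hit)]]
    colnames(vals) <- labels
  }
  structure(list(time = tt, values = vals, channel_labels = labels,
                 time_unit = detected),
            class = "sensor_series")
}

#' @export
print.sensor_series <- function(x, ...) {
  cat(sprintf("sensor_series: %d samples, %d channels, %.2f s span (unit %s)\n",
              length(x$time), ncol(x$values), diff(range(x$time)),
              x$time_unit))
  invisible(x)
}

#' Resample a raw sensor series onto an equidistant grid
#'
#' Linear interpolation of each channel onto a grid anchored at the first
#' timestamp with spacing `1/fsamp_target`; the output has
#' `floor((t_end - t_0) * fsamp_target) + 1` samples. Resampling is exact on
#' signals that are piecewise linear between input samples.
#'
#' @param raw a `sensor_series` (or list with `time` seconds and `values`).
#' @param fsamp_target target sampling frequency in Hz.
#' @return a [compound_signal()].
#' @export
resample_equidistant <- function(raw, fsamp_target) {
  if (fsamp_target <= 0) stop("fsamp_target must be positive")
  tt <- raw$time
  vals <- as.matrix(raw$values)
  if (length(tt) < 2L) stop("need at least two samples to resample")
  n1 <- floor((tt[length(tt)] - tt[1]) * fsamp_target + 1e-9)
  grid <- tt[1] + (0:n1) / fsamp_target
  out <- vapply(seq_len(ncol(vals)), function(j) {
    stats::approx(tt, vals[, j], xout = grid, method = "linear",
                  rule = 2)$y
  }, numeric(length(grid)))
  out <- matrix(out, ncol = ncol(vals),
                dimnames = list(NULL, colnames(vals)))
  compound_signal(out, fsamp = fsamp_target)
}

# Centered moving average with clamped partial windows at the edges.
moving_avg_centered <- function(x, wlen) {
  wlen <- max(1L, as.integer(wlen))
  n <- length(x)
  lo <- pmax(1L, seq_len(n) - (wlen - 1L) %/% 2L)
  hi <- pmin(n, seq_len(n) + wlen %/% 2L)
  cs <- cumsum(c(0, x))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Derive virtual channels from raw sensor axes
#'
#' Appends the acceleration magnitude `AM(n) = sqrt(ax^2 + ay^2 + az^2)`
#' (channel `"am"`) and/or the angular velocity energy `GE(n)`, a centered
#' moving average of `gx^2 + gy^2 + gz^2` (channel `"ge"`). The smoothing
#' window is short relative to a stride (`Nmin / 2` samples by default) so
#' the zero-velocity plateau of mid-stance stays resolvable.
#'
#' @param signal a [compound_signal()] with channels `acc_x/acc_y/acc_z`
#'   and/or `gyr_x/gyr_y/gyr_z`.
#' @param which subset of `c("AM", "GE")`.
#' @param config optional [cyclicity_config()] supplying `Nmin` for the GE
#'   smoothing window; a 0.5--3 Hz band is assumed otherwise.
#' @param ge_window explicit GE smoothing window length in samples.
#' @return the signal with the derived channels appended; existing channels
#'   are unchanged.
#' @export
derive_channels <- function(signal, which = c("AM", "GE"), config = NULL,
                            ge_window = NULL) {
  which <- match.arg(which, c("AM", "GE"), several.ok = TRUE)
  out <- signal$samples
  if ("AM" %in% which) {
    need <- c("acc_x", "acc_y", "acc_z")
    if (!all(need %in% signal$channel_labels))
      stop("AM requires channels ", paste(need, collapse = ", "))
    am <- sqrt(rowSums(out[, need, drop = FALSE]^2))
    out <- cbind(out, am = am)
  }
  if ("GE" %in% which) {
    need <- c("gyr_x", "gyr_y", "gyr_z")
    if (!all(need %in% signal$channel_labels))
      stop("GE requires channels ", paste(need, collapse = ", "))
    if (is.null(ge_window)) {
      Nmin <- if (!is.null(config)) config$Nmin
              else max(2L, as.integer(round(signal$fsamp / 3)))
      ge_window <- max(1L, as.integer(round(Nmin / 2)))
    }
    energy <- rowSums(out[, need, drop = FALSE]^2)
    out <- cbind(out, ge = moving_avg_centered(energy, ge_window))
  }
  compound_signal(out, fsamp = signal$fsamp)
}

#' Write a compound signal (or raw series) as a delimited table
#'
#' @param x a `compound_signal` or `sensor_series`.
#' @param path output file path.
#' @param sep field separator.
#' @export
write_sensor_table <- function(x, path, sep = ",") {
  df <- if (inherits(x, "compound_signal")) as.data.frame(x)
        else data.frame(t = x$time, x$values, check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
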