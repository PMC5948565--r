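#' Multi-channel equidistant inertial signal
#'
#' Container for an equidistantly sampled compound signal X(n, s): rows are
#' time indices n (0-based; the time of index n is n/fsamp seconds), columns
#' are sensor channels s. All stride positions produced by the package are
#' 0-based sample indices into this grid.
#'
#' @param samples numeric matrix (or vector for a single channel), one row
#'   per sample, one column per channel.
#' @param fsamp sampling frequency in Hz (> 0).
#' @param channel_labels character vector naming the channels; defaults to
#'   the matrix column names.
#' @return an object of class `compound_signal` with fields `samples`,
#'   `channel_labels` and `fsamp`.
#' @examples
#' sig <- compound_signal(cbind(acc_x = sin(1:100 / 4)), fsamp = 25)
#' signal_length(sig)
#' @export
compound_signal <- function(samples, fsamp, channel_labels = NULL) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1)
  samples <- as.matrix(samples)
  if (!is.numeric(samples)) stop("samples must be numeric")
  if (nrow(samples) < 1L) stop("signal must contain at least one sample")
  if (!is.numeric(fsamp) || length(fsamp) != 1L || fsamp <= 0)
    stop("fsamp must be a single positive number")
  if (is.null(channel_labels)) channel_labels <- colnames(samples)
  if (is.null(channel_labels))
    channel_labels <- paste0("ch", seq_len(ncol(samples)))
  if (length(channel_labels) != ncol(samples))
    stop("channel_labels must match the number of channels")
  colnames(samples) <- channel_labels
  structure(
    list(samples = samples, channel_labels = channel_labels,
         fsamp = as.numeric(fsamp)),
    class = "compound_signal"
  )
}

#' Number of samples in a compound signal
#' @param x a `compound_signal`.
#' @return integer sample count (the signal length \eqn{\ell}).
#' @export
signal_length <- function(x) nrow(x$samples)

#' Number of channels in a compound signal
#' @param x a `compound_signal`.
#' @export
n_channels <- function(x) ncol(x$samples)

#' Extract one channel of a compound signal
#' @param x a `compound_signal`.
#' @param label channel label or column index.
#' @return numeric vector of the channel's samples.
#' @export
channel_values <- function(x, label) {
  if (is.character(label) && !label %in% x$channel_labels)
    stop("unknown channel: ", label)
  x$samples[, label]
}

#' @export
print.compound_signal <- function(x, ...) {
  cat(sprintf("compound_signal: %d samples x %d channels @ %g Hz (%.2f s)\n",
              signal_length(x), n_channels(x), x$fsamp,
              signal_length(x) / x$fsamp))
  cat("channels:", paste(x$channel_labels, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.compound_signal <- function(x, ...) {
  data.frame(t = (seq_len(signal_length(x)) - 1) / x$fsamp,
             x$samples, check.names = FALSE)
}
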