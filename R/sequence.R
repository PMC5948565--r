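#' Extract gait sequences by backtracing
#'
#' Partitions time-sorted stride triplets of one component into gait
#' sequences. Walking backwards from the latest stride, the observed
#' inter-stride interval is compared with the globally tracked stride time:
#' `Delta = |(t_i - t_{i-1}) - g(t_i)|`. While `Delta < Nmin` the previous
#' stride joins the current sequence; otherwise the sequence is closed and a
#' new one starts. A sequence's onset is one stride time before its first
#' detected fiducial (`t_first - d_first`, clamped at 0) and its termination
#' is the position of its last stride, so gaps between sequences are the
#' silences of the recording.
#'
#' @param triplets data frame (`t`, `d`, `v`) sorted ascending by `t`.
#' @param track a [build_track()] result.
#' @param Nmin shortest admissible stride time in samples.
#' @return a list of class `gait_sequences`; each element has `onset`,
#'   `send`, `members` (row indices into `triplets`) and `reliability`
#'   (`NA` until [score_sequences()] fills it).
#' @export
extract_sequences <- function(triplets, track, Nmin) {
  n <- nrow(triplets)
  out <- list()
  if (n == 0L) return(structure(out, class = "gait_sequences"))
  if (is.unsorted(triplets$t)) stop("triplets must be sorted by t")
  close_seq <- function(members) {
    i1 <- members[1]
    list(onset = max(0L, triplets$t[i1] - triplets$d[i1]),
         send = triplets$t[members[length(members)]],
         members = members, reliability = NA_real_)
  }
  members <- n
  if (n > 1L) {
    for (i in (n - 1L):1L) {
      delta <- abs((triplets$t[i + 1L] - triplets$t[i]) -
                     track_at(track, triplets$t[i + 1L]))
      if (delta < Nmin) {
        members <- c(i, members)
      } else {
        out[[length(out) + 1L]] <- close_seq(members)
        members <- i
      }
    }
  }
  out[[length(out) + 1L]] <- close_seq(members)
  structure(rev(out), class = "gait_sequences")
}

#' Score gait sequences by agreement with the global track
#'
#' Fills each sequence's reliability: the mean absolute error between the
#' member stride times and the globally tracked stride time at the member
#' positions, `mean(|d - g(t)|)`. Lower is more reliable.
#'
#' @param sequences a `gait_sequences` list.
#' @param triplets the triplets the sequences index into.
#' @param track a [build_track()] result.
#' @return the sequences with `reliability` filled.
#' @export
score_sequences <- function(sequences, triplets, track) {
  for (j in seq_along(sequences)) {
    m <- sequences[[j]]$members
    sequences[[j]]$reliability <-
      mean(abs(triplets$d[m] - track_at(track, triplets$t[m])))
  }
  sequences
}

#' @export
print.gait_sequences <- function(x, ...) {
  cat(sprintf("gait_sequences: %d sequence(s)\n", length(x)))
  for (j in seq_along(x))
    cat(sprintf("  [%d] onset %d, end %d, %d stride(s), reliability %s\n",
                j, x[[j]]$onset, x[[j]]$send, length(x[[j]]$members),
                format(x[[j]]$reliability, digits = 3)))
  invisible(x)
}

#' @export
as.data.frame.gait_sequences <- function(x, ...) {
  data.frame(
    sequence = seq_along(x),
    onset = vapply(x, `[[`, integer(1), "onset"),
    send = vapply(x, `[[`, integer(1), "send"),
    n_strides = vapply(x, function(s) length(s$members), integer(1)),
    reliability = vapply(x, `[[`, numeric(1), "reliability"))
}
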