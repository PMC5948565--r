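# run expr under a local RNG seed without disturbing the caller's stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

gauss_bump <- function(phase, center, width) {
  exp(-((phase - center) / width)^2 / 2)
}

#' Built-in intra-stride waveform templates
#'
#' Each template is a waveform over intra-stride phase `[0, 1)` built from a
#' few Gaussian bumps, with a designated fiducial phase and the fiducial
#' kind it exercises: `"peak"` carries one dominant positive peak (maxima
#' fiducials), `"trough"` one dominant trough (minima), `"zerocross"` a
#' steep sign change (zero-crossing fiducials). Variant `"b"` keeps the
#' fiducial phase but changes the secondary morphology, so transitions can
#' morph between variants without moving the ground-truth event.
#'
#' @param kind `"peak"`, `"trough"` or `"zerocross"`.
#' @param variant `"a"` or `"b"`.
#' @return list of class `gait_template`: `fun(phase)`, `fid_phase`,
#'   `fid_kind`.
#' @export
gait_template <- function(kind = c("peak", "trough", "zerocross"),
                          variant = c("a", "b")) {
  kind <- match.arg(kind); variant <- match.arg(variant)
  tpl <- switch(kind,
    peak = if (variant == "a")
      list(fun = function(p) gauss_bump(p, 0.25, 0.07) -
             0.35 * gauss_bump(p, 0.6, 0.12) + 0.2 * gauss_bump(p, 0.82, 0.08),
           fid_phase = 0.25, fid_kind = "M")
    else
      list(fun = function(p) gauss_bump(p, 0.25, 0.055) -
             0.2 * gauss_bump(p, 0.5, 0.1) + 0.45 * gauss_bump(p, 0.75, 0.1),
           fid_phase = 0.25, fid_kind = "M"),
    trough = if (variant == "a")
      list(fun = function(p) -gauss_bump(p, 0.3, 0.07) +
             0.3 * gauss_bump(p, 0.68, 0.12),
           fid_phase = 0.3, fid_kind = "m")
    else
      list(fun = function(p) -gauss_bump(p, 0.3, 0.09) +
             0.5 * gauss_bump(p, 0.6, 0.08) - 0.15 * gauss_bump(p, 0.85, 0.06),
           fid_phase = 0.3, fid_kind = "m"),
    zerocross = if (variant == "a")
      list(fun = function(p) gauss_bump(p, 0.35, 0.1) -
             gauss_bump(p, 0.65, 0.1),
           fid_phase = 0.5, fid_kind = "z")
    else
      list(fun = function(p) 0.8 * gauss_bump(p, 0.33, 0.08) -
             1.1 * gauss_bump(p, 0.67, 0.12),
           fid_phase = 0.5, fid_kind = "z"))
  structure(tpl, class = "gait_template")
}

#' Sample a stride-time process
#'
#' Stride times follow a bounded Gaussian random walk,
#' `T_i = clip(T_{i-1} + N(0, sigma_T), T_lo, T_hi)`, emulating the slow
#' drift of self-selected walking cadence. Default bounds `[1/1.2, 1/0.55]`
#' seconds span the stride-frequency range observed in free-walking IMU
#' recordings (0.55--1.2 Hz).
#'
#' @param n_strides number of strides (>= 1).
#' @param T0 initial stride time in seconds.
#' @param sigma_T random-walk step standard deviation in seconds.
#' @param bounds admissible stride-time interval `[T_lo, T_hi]` in seconds.
#' @param start_s onset of the first stride in seconds.
#' @param seed optional RNG seed (restores the caller's RNG state).
#' @return data frame with `onset_s` (stride onsets, cumulative) and `T_s`
#'   (stride times).
#' @export
sample_stride_process <- function(n_strides, T0 = 1.1, sigma_T = 0.02,
                                  bounds = c(1 / 1.2, 1 / 0.55),
                                  start_s = 1, seed = NULL) {
  if (n_strides < 1L) stop("n_strides must be >= 1")
  if (!(bounds[1] < bounds[2])) stop("invalid stride-time bounds")
  if (T0 < bounds[1] || T0 > bounds[2]) stop("T0 outside bounds")
  with_seed(seed, {
    Tt <- numeric(n_strides)
    prev <- T0
    for (i in seq_len(n_strides)) {
      Tt[i] <- min(max(prev + stats::rnorm(1, 0, sigma_T), bounds[1]),
                   bounds[2])
      prev <- Tt[i]
    }
    data.frame(onset_s = start_s + cumsum(c(0, Tt[-n_strides])), T_s = Tt)
  })
}

#' Render a synthetic multi-channel inertial gait trial
#'
#' Turns a stride-time process into a sampled compound signal with
#' exhaustive ground truth. Each stride renders its channel template warped
#' linearly to the stride time, with per-stride amplitude jitter; channels
#' are shifted by per-channel fiducial delays; an optional block of strides
#' is silenced (a gap splitting the recording into gait sequences) and an
#' optional block morphs linearly between template variants (a transition).
#' White Gaussian noise is added at the stated SNR, measured on the active
#' (non-gap) portion of each channel.
#'
#' @param process a [sample_stride_process()] data frame.
#' @param templates named list of `gait_template`s, one per channel.
#' @param delays named integer vector of per-channel fiducial delays in
#'   samples (`|delay| <= Nmax`); default 0.
#' @param snr_db signal-to-noise ratio in dB; `Inf` for noiseless.
#' @param gap `NULL`, or list with `after` (last stride index of the first
#'   sequence) and `n_strides` (strides consumed by the silence).
#' @param transition `NULL`, or list with `at` (first morphing stride) and
#'   `n_strides` (morph length).
#' @param fsamp sampling frequency in Hz.
#' @param amp_jitter relative per-stride amplitude jitter (uniform).
#' @param margin_s silent margin before/after the gait in seconds.
#' @param seed optional RNG seed.
#' @return object of class `synthetic_trial`: `signal` (a
#'   [compound_signal()]), `truth` (data frame `channel`, `stride_index`,
#'   `t_truth`, `sequence_id`, `is_transition`), `sequences` (per-channel
#'   truth bounds), `stride_times` (samples, per kept stride), `delays`,
#'   `params`, `seed`.
#' @export
render_trial <- function(process, templates, delays = NULL, snr_db = 10,
                         gap = NULL, transition = NULL, fsamp = 25,
                         amp_jitter = 0.1, margin_s = 1, seed = NULL) {
  channels <- names(templates)
  if (is.null(channels)) stop("templates must be a named list (channels)")
  for (tp in templates)
    if (is.null(tp$fid_phase)) stop("template lacks a fiducial phase")
  if (is.null(delays)) delays <- stats::setNames(rep(0L, length(channels)),
                                                 channels)
  delays <- delays[channels]
  delays[is.na(delays)] <- 0L

  n_all <- nrow(process)
  removed <- integer(0)
  seq_id <- rep(1L, n_all)
  if (!is.null(gap)) {
    removed <- seq.int(gap$after + 1L, min(n_all, gap$after + gap$n_strides))
    if (max(removed) >= n_all)
      stop("gap would consume the trailing strides")
    seq_id[(max(removed) + 1L):n_all] <- 2L
  }
  morph_alpha <- rep(0, n_all)
  if (!is.null(transition)) {
    idx <- seq.int(transition$at,
                   min(n_all, transition$at + transition$n_strides - 1L))
    morph_alpha[idx] <- seq_along(idx) / length(idx)
  }
  kept <- setdiff(seq_len(n_all), removed)

  t_end <- process$onset_s[n_all] + process$T_s[n_all]
  ell <- as.integer(ceiling((t_end + margin_s) * fsamp)) + 1L
  tgrid <- (0:(ell - 1L)) / fsamp

  with_seed(seed, {
    X <- matrix(0, ell, length(channels),
                dimnames = list(NULL, channels))
    truth <- list()
    for (ci in seq_along(channels)) {
      ch <- channels[ci]
      tplA <- templates[[ch]]
      tplB <- gait_template(
        switch(tplA$fid_kind, M = "peak", m = "trough", z = "zerocross",
               "peak"), "b")
      base <- numeric(ell)
      for (i in kept) {
        on <- process$onset_s[i]; Ti <- process$T_s[i]
        idx <- which(tgrid >= on & tgrid < on + Ti)
        if (!length(idx)) next
        phase <- (tgrid[idx] - on) / Ti
        amp <- 1 + stats::runif(1, -amp_jitter, amp_jitter)
        a <- morph_alpha[i]
        val <- if (a > 0) (1 - a) * tplA$fun(phase) + a * tplB$fun(phase)
               else tplA$fun(phase)
        base[idx] <- base[idx] + amp * val
      }
      lam <- as.integer(delays[ci])
      X[, ci] <- shift_vector(base, lam)
      if (is.finite(snr_db)) {
        active <- which(shift_vector(as.numeric(base != 0), lam) > 0)
        rms <- sqrt(mean(X[active, ci]^2))
        X[, ci] <- X[, ci] + stats::rnorm(ell, 0, rms / 10^(snr_db / 20))
      }
      truth[[ch]] <- data.frame(
        channel = ch, stride_index = kept,
        t_truth = as.integer(round((process$onset_s[kept] +
                                      tplA$fid_phase * process$T_s[kept]) *
                                     fsamp)) + lam,
        sequence_id = seq_id[kept],
        is_transition = morph_alpha[kept] > 0)
    }
    truth <- do.call(rbind, truth)
    rownames(truth) <- NULL

    # per-channel ground-truth sequence bounds in the detector's semantics:
    # onset one stride time before the first fiducial, end at the last one
    seqs <- do.call(rbind, lapply(channels, function(ch) {
      tr <- truth[truth$channel == ch, ]
      do.call(rbind, lapply(unique(tr$sequence_id), function(sid) {
        ts <- tr$t_truth[tr$sequence_id == sid]
        first <- tr$stride_index[tr$sequence_id == sid][1]
        d1 <- as.integer(round(process$T_s[first] * fsamp))
        data.frame(channel = ch, sequence_id = sid,
                   onset = max(0L, ts[1] - d1), send = ts[length(ts)])
      }))
    }))
    rownames(seqs) <- NULL

    structure(list(
      signal = compound_signal(X, fsamp = fsamp),
      truth = truth, sequences = seqs,
      stride_times = as.integer(round(process$T_s[kept] * fsamp)),
      kept_strides = kept, removed_strides = removed,
      delays = delays,
      params = list(snr_db = snr_db, gap = gap, transition = transition,
                    fsamp = fsamp, amp_jitter = amp_jitter,
                    margin_s = margin_s),
      seed = seed),
      class = "synthetic_trial")
  })
}

#' Default synthetic gait trial
#'
#' The package's reference test condition: roughly one minute of gait at
#' 25 Hz sampling, SNR 10 dB, one silent gap splitting the recording into
#' two gait sequences, and one morphological transition. Three channels
#' exercise the three automatic fiducial kinds: `acc_x` (dominant positive
#' peak), `acc_y` (dominant trough), `gyr_z` (steep zero-crossing), with
#' small per-channel fiducial delays.
#'
#' @param seed RNG seed; the trial is deterministic given the seed.
#' @param duration_s approximate total duration in seconds.
#' @param fsamp sampling frequency in Hz.
#' @param snr_db signal-to-noise ratio in dB.
#' @param n_gaps 0 or 1 silent gaps.
#' @param n_transitions 0 or 1 template transitions.
#' @return a [render_trial()] object.
#' @export
synthetic_trial <- function(seed = 1, duration_s = 60, fsamp = 25,
                            snr_db = 10, n_gaps = 1, n_transitions = 1) {
  T0 <- 1.1
  gap_s <- 5
  # stand-still margins longer than one analysis window (Nmax = 2 s) keep
  # every labelled stride inside the observable region
  margin_s <- 2.5
  n <- max(4L, as.integer(floor((duration_s - 2 * margin_s) / T0)))
  process <- sample_stride_process(n, T0 = T0, sigma_T = 0.02,
                                   start_s = margin_s,
                                   seed = seed * 13L + 1L)
  gap <- NULL
  if (n_gaps > 0) {
    after <- n %/% 2L
    # never consume the trailing strides of a short trial
    k <- min(max(1L, as.integer(round(gap_s / T0))), n - after - 2L)
    if (k >= 1L) gap <- list(after = after, n_strides = k)
  }
  transition <- NULL
  if (n_transitions > 0)
    transition <- list(at = max(2L, n %/% 4L), n_strides = 6L)
  templates <- list(acc_x = gait_template("peak"),
                    acc_y = gait_template("trough"),
                    gyr_z = gait_template("zerocross"))
  render_trial(process, templates,
               delays = c(acc_x = 0L, acc_y = 2L, gyr_z = -3L),
               snr_db = snr_db, gap = gap, transition = transition,
               fsamp = fsamp, margin_s = margin_s,
               seed = seed * 13L + 2L)
}

#' @export
print.synthetic_trial <- function(x, ...) {
  cat(sprintf(
    "synthetic_trial: %d strides (%d removed by gaps), %d channels, %.1f s @ %g Hz\n",
    length(x$kept_strides), length(x$removed_strides),
    n_channels(x$signal), signal_length(x$signal) / x$signal$fsamp,
    x$signal$fsamp))
  cat(sprintf("  SNR %s dB, delays: %s\n", format(x$params$snr_db),
              paste(names(x$delays), x$delays, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Write a synthetic trial as signal table plus truth sidecar
#'
#' @param trial a `synthetic_trial`.
#' @param prefix output path prefix; writes `<prefix>_signal.csv` and
#'   `<prefix>_truth.csv`.
#' @return invisibly, the two file paths.
#' @export
write_trial <- function(trial, prefix) {
  sig_path <- paste0(prefix, "_signal.csv")
  truth_path <- paste0(prefix, "_truth.csv")
  write_sensor_table(trial$signal, sig_path)
  utils::write.table(trial$truth, truth_path, sep = ",",
                     row.names = FALSE, quote = FALSE)
  invisible(c(signal = sig_path, truth = truth_path))
}
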