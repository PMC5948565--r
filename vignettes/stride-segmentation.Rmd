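---
title: "Stride segmentation by local cyclicity estimation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stride segmentation by local cyclicity estimation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strideseg)
```

## The problem and the model

Walking is a cyclostationary process: the inertial signature of each stride
resembles that of its neighbours, while the stride time (the interval
between successive occurrences of the same gait event) drifts slowly with
cadence and changes abruptly at transitions. `strideseg` segments strides in
multi-channel inertial recordings without templates, training, or prior
knowledge of the sensor placement. Instead of detecting individual peaks, it
tracks the *local fundamental period* of the signal — a pitch-tracking view
of gait — and reconstructs stride positions afterwards.

The pipeline has four stages:

1. **Stride-time estimation.** Analysis windows of half-width `Nmax` slide
   over the signal with step `eta`. Within each window, each selected local
   cyclicity estimator scores every admissible stride time
   `N ∈ [Nmin, Nmax]` by comparing the presumed current stride `w(0..N-1)`
   against the presumed previous stride `w(-N..-1)`. Scores become posterior
   curves (shift to zero, normalize), and posteriors multiply across
   estimators (per channel) and across channels (globally), in the Bayesian
   spirit of interval estimation from ballistocardiography. The per-channel
   posterior maximum doubles as the window's stride confidence `v`.
2. **Stride positioning.** Given a window's stride time, a fiducial-point
   function picks the lag of the gait event inside the window's right half;
   paired with its counterpart one stride earlier. Because `eta` is much
   smaller than the window, each true fiducial receives about `d/eta`
   replicated votes; votes are consolidated by majority position (±1 sample
   merge), modal stride time, and mean confidence, and groups with too few
   votes (`count/l_exp ≤ h`) are discarded. Confidence (`hv`) and
   noise-variability (`hr`) thresholds remove unreliable and silent-region
   strides.
3. **Sequence extraction.** Walking backwards through the consolidated
   strides, the observed inter-stride interval is compared with the global
   stride-time track `g(n)` (nearest-neighbour interpolation of the fused
   window estimates): a discrepancy of `Nmin` or more closes the gait
   sequence. Sequence reliability is the mean `|d − g(t)|` of its members.
4. **Fusion and enhancement.** Each component's strides become a sparse
   confidence vector; components are aligned to a reference component by
   normalized cross-correlation (one lag per gait sequence), stacked,
   marginalized, smoothed with a triangular window, and the peaks of the
   smoothed trace — thresholded by the valley of a kernel density estimate
   over peak heights — are the final strides.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `fmin`, `fmax` | 0.5, 3 Hz | physiological stride-frequency band; gives `Nmax = round(fsamp/fmin)` (2 s) and `Nmin = max(2, round(fsamp/fmax))` (1/3 s) |
| `eta` | `round(0.1 s · fsamp)` | window step; ~30 % of the shortest admissible stride, giving each fiducial `≈ d/eta` votes |
| `estimators` | 1–4 | autocorrelation, inverted average magnitude difference, maximum amplitude pairs, banded DTW |
| `hv` | 0.11 | stride confidence threshold; the precision/recall intersection protocol converges near this value on real smartphone data |
| `hr` | 0 (off) | minimal expected per-stride dynamic range in channel units; set from sensor noise or known activity level |
| `h` | 0.75 | replication-ratio gate, "close to 1" but tolerant of boundary windows |
| `merge_tol` | 1 sample | vote-merge radius; noise misplaces detections by a few samples |
| `fusion_window` | `Nmin` | length of the triangular fusion window (see below) |

The DTW estimator uses a Sakoe–Chiba band of radius `max(2, N/10)` (rounded
half away from zero): cost `O(N·band)` while absorbing the small intra-stride
warps it exists to tolerate.

## Numerical choices and tie-breaks

* **Score → posterior mapping.** Scores are shifted so the minimum is zero
  and normalized to unit sum. This is robust to negative correlation scores
  and introduces no temperature hyperparameter (a softmax was rejected for
  that reason). A flat score vector maps to the uniform distribution.
* **Probability floor.** Posterior products apply a floor of `1e-12` per
  element (in log space), so one dissenting estimator cannot annihilate a
  candidate period.
* **Ties.** Posterior argmax ties (relative tolerance `1e-9`) break toward
  the smallest admissible `N`, biasing against period doubling: a strictly
  periodic signal of period `P ≤ Nmax/2` scores identically at `P` and `2P`
  for the difference- and warping-based estimators. Alignment-lag ties break
  toward the smallest `|τ|`, then negative; modal stride-time ties toward
  the smaller `d`; zero-energy plateau ties toward the earlier run.
* **Expected vote count.** The replication gate compares the group size with
  `l_exp = min(d, t)/eta`: only windows whose right half can contain the
  fiducial can vote for it. The variant `l_exp = t/eta` (which grows with
  absolute time and starves the gate late in a recording) is available as
  `lexp_rule = "printed"` for comparison.
* **Fusion window length.** A unit-area triangular window whose support
  reaches the neighbouring stride performs exact linear interpolation
  between equal-confidence spikes: with stride spacing `s` and half-width
  `h = s`, the smoothed trace is analytically constant and every stride
  peak vanishes. Since typical stride times (0.8–1.8 s) are close to
  `Nmax/2`, a window of length `Nmax` is degenerate in exactly the regime
  the method targets. The default is therefore `Nmin`: replication scatter
  of a few samples merges into one peak, while every admissible stride
  spacing (`≥ Nmin`) remains resolvable.
* **Alignment smearing.** Sparse trains are smeared with a narrow triangle
  (half-width 2) before cross-correlation; exact-coincidence correlation of
  delta trains is brittle under the ±1–2-sample scatter the merge step
  tolerates. Both trains receive the same symmetric kernel, which preserves
  the argmax lag on clean trains. Reference-sequence spans with fewer than
  three reference spikes (or fewer than two component spikes) fall back to
  the globally estimated lag.
* **KDE peak threshold.** Peak heights are thresholded at the minimum of a
  Gaussian KDE (Silverman bandwidth) between its two largest modes — but
  only when that valley falls below 75 % of the smaller mode. Genuine
  silence-region junk separates from true strides by an order of magnitude;
  ripples inside one height cluster do not, and a unimodal (or degenerate)
  height distribution keeps every peak, preserving the unsupervised design.
* **Final stride times.** `d_i = t_{i+1} − t_i` between surviving peaks
  (the variant mixing the next maximum with the current minimum is available
  as `d_rule = "printed"`). Intervals outside `[Nmin, Nmax]` — sequence
  boundaries and gaps — are reported as `NA` rather than as stride times.
* **Degenerate inputs.** A constant window yields the uniform posterior and
  `Nmin`; a signal shorter than one analysis window yields an empty series
  with a warning; a component with no reliable strides is dropped before
  fusion; zero-energy sparse vectors align at lag 0 with a warning.

## The synthetic generator: what it emulates, and what it does not

`synthetic_trial()` renders quasi-periodic multi-channel gait:

* stride times follow a bounded Gaussian random walk
  (`T_i = clip(T_{i-1} + N(0, 0.02 s), 0.83, 1.82 s)`, i.e. the 0.55–1.2 Hz
  stride-frequency range observed in free walking, starting at 1.1 s);
* per-channel intra-stride templates are sums of 2–4 Gaussian bumps over
  phase with a designated fiducial: a dominant positive peak (`acc_x`,
  maxima), a dominant trough (`acc_y`, minima), and a steep sign change
  (`gyr_z`, zero-crossings), with per-channel fiducial delays of 0, +2 and
  −3 samples;
* per-stride amplitude jitter (±10 %), one silent gap (~5 s, longer than
  `Nmax`) splitting the recording into two gait sequences, one
  morphological transition (six strides morphing linearly to a second
  template variant with the same fiducial phase), and white Gaussian noise
  at 10 dB SNR measured on the active portion of each channel;
* 2.5 s stand-still margins — longer than one analysis window — so every
  labelled stride lies in the observable region;
* exhaustive ground truth: per-channel fiducial samples, stride times,
  sequence bounds (in the detector's semantics: onset one stride before the
  first fiducial, end at the last), and transition flags. Trials are
  byte-reproducible from their seed.

The default study condition is one minute at 25 Hz — the smartphone-style
sampling rate at which one sample is 40 ms — which keeps the full test
suite and the acceptance script within seconds on a single CPU.

What the generator does **not** emulate: biomechanically realistic gait
dynamics, coloured or drifting sensor noise, sensor re-orientation within a
recording, non-gait activity (the gaps are pure noise), or asymmetric
left/right gait. Passing the synthetic checks therefore demonstrates that
the algorithm recovers what it models — periods, positions, lags, sequences
— under controlled degradation; it does not certify performance on any
particular real dataset or population.

## The canonical evaluation protocol

`run_default_trial()` segments the default trial with all four estimators
on all channels and maxima/minima fiducials (`"1234-AccGyr-A-[M|m]"`), a
noise-variability threshold of 0.8 channel units (the templates have unit
nominal amplitude, so the minimal expected within-stride dynamic range is
about 1.1, while silence stays below ~0.7 at 10 dB SNR), and the designated
landmark component `acc_x[M]` fixed as the reference — mirroring the
a-priori manual reference choice that instrumented (shoe-sensor) protocols
use. Automatic reference selection remains available and is exercised in
the tests; it may legitimately settle on a component whose fiducial kind
carries a constant phase offset from the channel's designated landmark,
which is a valid segmentation but not comparable against the recorded
ground-truth instants.

Scoring follows the standard protocol: sample-level sequence coverage
(four-class confusion), stride matching within ±100 ms with the closest
detection winning per labelled border, absolute-error statistics
(nearest-rank P95), least-squares regression, Bland–Altman agreement
(`RPC = 1.96 σ` of the differences), and signed fiducial delays for bias.
The printed "recall" variant `FP/(FP+TN)` is exposed as `fall_out`;
F-scores use the standard `TP/(TP+FN)` recall.

## Known limitations

* Strides whose fiducial lies closer than `Nmax` to either end of the
  recording are structurally unobservable (no complete analysis window
  covers them).
* Isolated strides cannot be detected: the method assumes at least two
  consecutive strides in a window.
* The final stride of each sequence has no following peak, so its stride
  time is `NA`.
* Sub-sample fiducial precision is out of scope; all positions are integer
  sample indices.
* At 25 Hz, stride times whose doubled value is still admissible
  (`P ≤ Nmax/2`) are genuinely ambiguous for difference-based estimators on
  strictly periodic signals; the smallest-N tie-break resolves this in
  favour of the fundamental.
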