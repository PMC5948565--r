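# strideseg

Template-free, unsupervised stride segmentation, gait sequence extraction,
and gait event detection for multi-channel inertial signals (accelerometer,
gyroscope, magnetometer — smartphones or body-mounted IMUs).

Most stride segmenters detect individual peaks or match stride templates.
`strideseg` instead treats gait as a cyclostationary process and tracks its
local fundamental period, the way a pitch tracker follows a voice. For each
sliding analysis window \(W_k\) and each channel \(s\), a bank of local
cyclicity estimators scores every admissible stride time
\(N \in [N_{min}, N_{max}]\) (derived from the physiological 0.5–3 Hz
stride-frequency band), and the scores fuse as Bayesian posteriors:

\[
N_{k,s} = \arg\max_N \; p(N\mid\theta_1^s)\cdots p(N\mid\theta_e^s),
\qquad
v_{k,s} = \max_N \; p(N\mid\theta_1^s)\cdots p(N\mid\theta_e^s)
\]

with autocorrelation, inverted average magnitude difference, maximum
amplitude pairs, and banded dynamic time warping as estimators
\(\theta_1 \dots \theta_4\). Fiducial-point functions (maxima, minima,
zero-crossings, abrupt changes, zero-energy plateaus) then convert each
window's stride time into a stride *position* \(t_{k,s} = n_k + f(w_{k,s},
N_{k,s})\); replicated votes from overlapping windows are consolidated into
unique stride triplets \((\hat d, \hat t, \hat v)\), partitioned into gait
sequences by backtracing against the global stride-time track \(g(n)\), and
finally fused across channels: sparse confidence trains are aligned by
cross-correlation, stacked, smoothed, and thresholded by the valley of a
kernel density estimate over peak heights.

The package also ships a synthetic gait-signal generator with exhaustive
ground truth (stride instants per channel, sequence bounds, transitions)
and the standard evaluation metrics: sample-level sequence coverage, stride
matching within ±100 ms, absolute-error statistics, least-squares
regression, Bland–Altman agreement (RPC = 1.96 σ), and the precision/recall
threshold-selection protocol.

## Worked example

```r
library(strideseg)

res <- run_default_trial(seed = 1)   # generate + segment + evaluate
res$trial
#> synthetic_trial: 44 strides (5 removed by gaps), 3 channels, 69.0 s @ 25 Hz
#>   SNR 10 dB, delays: acc_x=0, acc_y=2, gyr_z=-3
res$segmentation
#> gait_segmentation: 41 stride(s) in 4 sequence(s)
#>   reference component: acc_x[M]
#>   stride time: median 33 samples (1.32 s)
head(res$segmentation$strides)
#>     t  d         v sequence
#> 1  95 29 0.2999812        1
#> 2 124 30 0.3382370        1
#> ...
ev <- res$evaluation
sprintf("F = %.3f, MAE = %.3f samples, coverage F = %.3f",
        ev$match$f_score, ev$timing$ae$mean, ev$coverage$f_score)
#> "F = 0.965, MAE = 0.474 samples, coverage F = 0.951"
```

Each row of `strides` is one detected stride: position `t` (0-based sample
index; divide by `fsamp` for seconds), stride time `d` in samples (`NA` for
the last stride of a sequence, which has no successor), fused confidence
`v`, and the merged gait sequence it belongs to. The evaluation compares
the detections with the generator's ground truth for the reference channel:
stride-matching F-measure, mean absolute stride-time error in samples, and
sample-level sequence-coverage F.

For real recordings, start from a delimited sensor table:

```r
raw <- read_sensor_table("walk.csv")          # time column + channels
sig <- resample_equidistant(raw, fsamp = 25)  # linear interpolation
sig <- derive_channels(sig, c("AM", "GE"))    # optional virtual channels
seg <- segment_gait(sig, cyclicity_config(25, hr = 0.1),
                    spec = "1234-AccGyr-A-[M|m]")
```

A thin command-line wrapper with `segment`, `simulate` and `evaluate`
subcommands is installed at `inst/cli/strideseg`.

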