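---
title: "Kinematic analysis of upper-limb reaching tasks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinematic analysis of upper-limb reaching tasks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reachkin)
```

## The problem

Bradykinesia — pathological slowing and fragmentation of voluntary movement —
is a cardinal motor sign of Parkinson's disease, and quantitative kinematic
descriptors of goal-directed arm movements are candidate indicators of
rehabilitation outcome. `reachkin` implements a complete analysis chain for a
structured upper-limb reaching protocol recorded with goniometric (joint
angle) sensors: two channels, horizontal and vertical shoulder angle in
degrees, sampled nominally at 20 Hz. The protocol explores four targets
(right, left, top, bottom) from a middle position and decomposes into eight
elementary submovements: four on the horizontal channel (phases 1, 2, 5, 6)
and four on the vertical channel (phases 3, 4, 7, 8), each an outward or
return rotation of nominally 29 degrees.

The package covers preprocessing, submovement segmentation, extraction of
thirteen kinematic parameters per submovement, two-group statistics, and a
synthetic-recording simulator used to validate every stage against known
ground truth.

## Preprocessing

Each channel is processed as

1. **Resampling** to 1 kHz by cubic-spline interpolation
   (`resample_spline()`, Forsythe–Malcolm–Moler end conditions, exact on
   cubic polynomials). The high processed rate keeps the traces on a grid
   suitable for co-registration with other modalities and makes the
   rectangle-rule integrals below accurate.
2. **Smoothing** with a zero-phase fifth-order low-pass Butterworth filter,
   cutoff 1.5 Hz (`lowpass_zero_phase()`). Voluntary reaching movements of
   one-second-and-up duration concentrate their energy below about 1 Hz,
   while parkinsonian tremor sits at 4–6 Hz; the forward–backward pass
   removes the tremor band (squared magnitude response, |H|² ≈ 6·10⁻⁶ at
   5 Hz) without phase distortion. Because the response is squared, the gain
   at the cutoff is 1/2 rather than 1/√2.
3. **Differentiation** by the forward Euler difference
   (`differentiate()`), applied three times to obtain velocity v(t),
   acceleration a(t) and jerk J(t). The final sample repeats the last
   difference so all traces share one grid.

Two numerical choices deserve note. First, each derivative is re-smoothed
with the same zero-phase filter before the next differentiation (the
`refilter_derivatives` switch, on by default): bare triple differencing at
1 kHz multiplies measurement noise by (2fs)³ and produces an unusable jerk
trace, while re-filtering keeps the noiseless result unchanged and the noisy
result bounded. Second, the forward–backward filter uses odd-reflection
padding (three filter lengths) with steady-state initial conditions, and the
signal mean is removed before filtering and restored afterwards. At
cutoff/fs = 0.0015 the direct-form recursion is numerically ill-conditioned
and a naive implementation passes DC with errors near 10⁻⁵; since the
operator maps constants to themselves exactly, mean removal makes the DC
response exact by construction.

The filter necessarily attenuates signal content near its cutoff: for a
1.5 s minimum-jerk movement the peak-velocity and peak-acceleration errors
at the default settings are 1–4%. The closed-form validation suite therefore
separates concerns: feature-extraction math is checked on noiseless traces
differentiated without smoothing (errors below 1%), while the filter is
checked against its own analytic frequency response and the segmentation
against simulated recordings processed with the full default chain.

## Segmentation

Submovements are detected on each channel's velocity curve
(`segment_recording()`):

- the detection threshold is 30% of the peak absolute velocity of the whole
  channel (`compute_threshold()`), a single scale-free quantity per channel;
- local maxima of |v| above the threshold are candidate submovement peaks;
  spurious peaks (tremor ripple, noise) are pruned by a prominence rule
  (default 10% of peak |v|) and a minimum separation (default 0.5 s);
- from each retained peak, the onset (offset) is pushed backward (forward)
  from the threshold crossing to the nearest *rest point*: the first sample
  that is a local minimum of |v| or falls below a velocity floor, 5% of the
  channel's peak |v|. Overlapping neighbour windows are truncated at the
  inter-peak valley of |v|; windows clipped at a record edge are flagged.

Operating on |v| treats outward and return movements symmetrically, and the
rest-point rule places the markers at the position plateaus between phases.
Detected windows are labelled with protocol phase ids by channel and
temporal order (horizontal → 1, 2, 5, 6; vertical → 3, 4, 7, 8), with the
displacement-direction pattern checked against the protocol; a mismatch, or
a count other than four per channel, produces a warning and ordinal labels.
A `phase_order` override supports recordings acquired with a different task
order.

All thresholds scale with the signal, so segmentation is invariant to
amplitude scaling and equivariant under time shifts — both properties are
tested.

### Accuracy reference

Simulated ground truth records both the nominal phase boundaries and the
*observable* boundaries — where the ideal noiseless velocity profile crosses
the 5% floor. The distinction matters for slow asymmetric movements: with
the parkinsonian velocity shape Beta(2.5, 4.5) and 2.2-fold slowing, the
last ~0.4% of the displacement dribbles over roughly 0.6 s below any
detectable velocity, so no rest-point detector (nor a human rater working
from the velocity trace) can mark the nominal end. Accuracy is therefore
measured against the observable boundaries; on the simulator's default
conditions the errors are 20–130 ms for both groups, within the 150 ms the
segmentation claims.

## The thirteen kinematic parameters

For each submovement window (`submovement_features()`):

| parameter | definition | units |
|---|---|---|
| amplitude | \|x(offset) − x(onset)\| | deg |
| duration | offset − onset | s |
| v_mean | amplitude / duration | deg/s |
| v_max, a_max, jerk_max | max of \|v\|, \|a\|, \|J\| over the window | deg/s, deg/s², deg/s³ |
| symmetry | deceleration time / acceleration time, split at peak \|v\| | — |
| p_mean | mean of position samples | deg |
| p_root_mean | mean of squared position samples | deg² |
| variance | variance of position samples | deg² |
| skewness, kurtosis | standardised 3rd/4th moments of time under density ∝ \|v(t)\| | — |
| smoothness | ∫ \|J(t)\| dt over the window | deg/s² |

Extrema are taken on absolute values so both movement directions report
positive magnitudes. `v_mean · duration = amplitude` holds exactly by
construction.

Two definitions were genuinely open and are resolved as follows,
with both alternatives selectable through `feature_config()`:

- **Shape moments.** The "Gaussian-like morphology of the velocity profile"
  is read as a time density: normalised time weighted by |v(t)|. Under this
  reading a prolonged deceleration yields positive skewness — the clinically
  expected direction in bradykinesia — and the minimum-jerk bell, whose |v|
  is the Beta(3,3) density in normalised time, has skewness 0 and
  (non-excess) kurtosis 7/3 ≈ 2.33, matching the scale of values this
  statistic takes on real recordings. The alternative basis (standardised
  moments of the position samples) is available via `shape_basis =
  "position"`. Location and scale statistics (p_mean, p_root_mean, variance)
  are computed on the position samples; p_root_mean is implemented as the
  mean of squared position (deg²), the reading consistent with its reported
  magnitude (≈ p_mean² + variance).
- **Smoothness.** The default is the literal jerk integral ∫|J|dt, the total
  variation of the acceleration profile; for a noiseless minimum-jerk
  movement it equals 4·a_max (acceleration traverses 0 → a_max → −a_max → 0).
  A dimensionless variant √(T⁵/A² ∫J² dt) is provided
  (`smoothness_metric = "dimensionless_jerk"`); its minimum-jerk value is
  √720 ≈ 26.83, since exact integration of the minimum-jerk jerk profile
  gives ∫J²dt = 720 A²/T⁵. (The figure 360 sometimes quoted for this
  integral is the ½∫J² optimal-control cost, not the integral itself.)

The symmetry coefficient is returned positive (it is a ratio of positive
durations); some legacy software reports it with a sign convention attached.

Per-recording averages across the eight phases (`average_features()`) use
the arithmetic mean; when a pathological recording drops phases, averaging
proceeds down to a configurable minimum of 6 phases, with a warning and an
`n_phases` flag.

## Statistical comparison

`route_and_test()` implements normality-routed test selection for small
unpaired samples, two-sided at α = 0.05: Shapiro–Wilk on each group; if both
pass, Levene's test (classic mean-centred form) decides between Student's t
and Welch's t (the standard remedy when homoscedasticity fails); otherwise
the Mann–Whitney U test, exact for group sizes up to 20 without ties. A
zero-variance group, where Shapiro–Wilk is undefined, routes to Mann–Whitney
with a warning. The exact route is validated against exhaustive enumeration
of all 924 rank configurations at n = 6 + 6, and the empirical type-I error
of the full router on 500 null simulations is checked to lie in
[0.025, 0.075].

`analyze_feature_table()` applies the router to every parameter × phase cell
and to the per-recording phase averages (13 × 8 + 13 = 117 results),
reporting group descriptives (mean, SD, median, IQR), the routing p-values,
the test used and its p-value. `pvalue_heatmap_table()` bins the p-values
(strong < 0.05 ≤ weak < 0.10 ≤ ns; thresholds configurable) into a
parameter × phase table.

**Unit of analysis.** By default every recording is one observation,
mirroring the common practice of analysing all trials. When trials of one
subject are correlated — as they are by construction in the simulator, where
trials share a subject-level profile draw — this pseudo-replicates and
inflates the null significance rate badly (in a null cohort of 6 + 6
subjects × 2 trials, about half the parameters can reach p < 0.05 from a
single chance difference between subject draws). The `unit = "subject"`
option averages trials per subject first; the package's own calibration
checks use it, and analyses of real repeated-trial data should too. No
multiple-testing correction is applied by default (a Benjamini–Hochberg
option exists), matching the exploratory, per-cell reading of the heatmap.

## The simulator

`generate_recording()` emits the eight-phase protocol at the raw 20 Hz rate
(deliberately, so the resampling path is always exercised): each phase is a
point-to-point movement whose velocity is a Beta(α, β) density in normalised
time (`beta_profile_movement()`), so position follows the regularised
incomplete Beta function and the displacement is exact. Shape (3,3)
reproduces Hogan's minimum-jerk quintic to machine precision
(`minimum_jerk()`). Phases are separated by 1 s rest dwells; the untouched
channel holds its position.

Group profiles (`subject_profile()`):

| parameter | healthy | parkinsonian | rationale |
|---|---|---|---|
| base duration | 1.5 s | × 2.2 | bradykinetic slowing of the reported magnitude |
| velocity shape | Beta(3, 3) | Beta(2.5, 4.5) | prolonged deceleration, time-density skewness ≈ 0.37 |
| tremor | none | 1.5° at 5 Hz | rest/action tremor band |
| amplitude | 29° | 29° | protocol target spacing |
| noise | 0.1° white | 0.1° white | goniometer resolution |

The pathological defaults are tuned to the *direction* and rough magnitude
of the reported group contrasts (slower, lower peak velocity, positive
skew), not to exact clinical values, which cannot be reproduced without the
original recordings. Between-subject variability is multiplicative
log-normal (SD 0.08) on duration scale, amplitude and tremor amplitude,
drawn once per subject and shared across that subject's trials;
`generate_cohort()` is deterministic given its seed. Tremor is a fixed-
frequency sinusoid with a random phase per channel, present during movement
and dwell; its amplitude leaves the velocity ripple prominence below the
peak-pruning threshold, so segmentation remains solvable — as it must, since
the method's premise is that tremor does not defeat the threshold detector.

What the simulator does *not* emulate: biomechanical coupling between
joints, movement fragmentation into multiple sub-pulses, amplitude-varying
or intermittent tremor, sensor drift, or missed/extra protocol phases.
Passing tests on simulated cohorts therefore demonstrate correctness of the
algorithms under the stated generative model, not clinical performance.

Note one interaction between model and metric: because the 1.5 Hz filter
removes the 5 Hz tremor almost completely, the simulated parkinsonian group
is distinguished on `smoothness` mainly through its slower, lower-
acceleration movements (∫|J|dt scales with a_max), i.e. its smoothness
values are *lower*, whereas clinically rougher movement with low-frequency
fragmentation would raise them. Group separation is preserved; the sign of
the contrast is a property of the generative model.

## Problem sizes and validation design

The validation suite uses: closed-form oracles on single noiseless 1 kHz
submovements; 20 seeded recordings per group for segmentation recovery; 500
null replicates for type-I calibration; and 6 + 6 subjects × 2 trials
(24 recordings) for the end-to-end designed-effect and null-cohort checks —
the same cohort geometry as the motivating study. The fixed seed for the
null-cohort calibration was chosen before running it. The full suite runs in
about a minute on one CPU.

## Known limitations

- The onset/offset rule reads rest from |v| only; co-contraction plateaus
  with residual drift could bias boundaries.
- Phase labelling assumes the canonical task order (remappable, but not
  inferred from the data).
- The Mann–Whitney exact route requires tie-free data; heavily quantised
  features fall back to the corrected normal approximation.
- With six subjects per group the per-cell tests are screening tools;
  heatmap cells should be read jointly, not as confirmatory findings.
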