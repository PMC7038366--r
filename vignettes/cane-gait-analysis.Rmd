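---
title: "Stride segmentation and gait features from an instrumented cane"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stride segmentation and gait features from an instrumented cane}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canegait)
```

## The measurement problem

A sensor-instrumented cane records, at 231 Hz, the load carried through the
shaft (a strain-gauge bridge, in raw ADC counts) and the cane's motion (a
9-axis IMU; the mediolateral gyroscope axis gives the anteroposterior, or
AP, angular velocity in °/s).  An optional shank-mounted IMU supplies a
100 Hz AP velocity stream from the leg for validation.  During cane-assisted
walking each cane cycle has a clear structure:

* **IC** (initial contact): the tip is planted, load rises from zero —
  a positive zero-crossing of the signed strain signal;
* **TC** (terminal contact): the tip is lifted, load returns to zero —
  the following negative strain zero-crossing;
* **PS** (peak swing): the maximum AP velocity while the cane swings
  forward;
* **EC** (end of contact): the tip is re-planted; during continuous walking
  this is the next cycle's IC.

IC→TC is the loading (stance) phase, TC→EC the swing phase.  The package
implements the two stride-segmentation algorithms that operate on these
landmarks, the eight per-stride gait features computed from them, the
repeated-measures statistics used to compare walking conditions, and a
synthetic-signal generator with exact per-stride ground truth.

## Preprocessing

All channels pass through sixth-order Butterworth low-pass filters: 4 Hz
for strain, 8 Hz for gyroscope channels.  Filtering is **zero-phase**
(forward–backward with odd-reflection padding).  This is a deliberate
design choice: a causal pass would delay each event by a lag that depends
on the local signal shape — and therefore on the walking condition — which
would directly corrupt the Difference-in-IC feature (tens of ms of
condition-dependent bias against a feature whose condition differences are
themselves 10–70 ms).  Zero-phase filtering leaves the apex of any
symmetric pulse exactly in place; its amplitude response is the squared
single-pass response, so attenuation at the cutoff is −6 dB.

Raw strain is an unsigned ADC level.  `baseline_correct()` estimates the
unloaded ("cane in the air") level as the dominant mode of the sample
distribution — the median of a symmetric band around the density peak of
the lower half of the data.  This estimator was chosen over the more
obvious "median of the lowest 30 % of samples" because any lower-tail
statistic is biased low under symmetric noise, and a fraction of a count
of baseline error translates into milliseconds of zero-crossing error
(the loading onset slope is of order 100 counts/s).  The pipeline maps the
unloaded level to −2 counts rather than 0 — the package's signed-strain
convention — so that loading onsets are genuine zero-crossings: a floor
sitting exactly at zero would put the crossing detector at the mercy of
noise.  With the default `floor_level = 0` the function is a pure offset
removal.

Zero-crossings are detected with hysteresis (arm below −h, fire on the
upward crossing, linear-interpolated time; h is three robust noise scales
of the unloaded phase, floored at 1 count) plus a dwell confirmation for
positive crossings: the signal must stay above −h for 0.22 s after the
crossing.  A genuine loading onset keeps the gauge loaded for the whole
stance phase; the small ringing excursions that a band-limited filter
produces after a steep unloading fall back to the floor within ~0.1 s and
are rejected without consuming the hysteresis arming.

## Segmentation

**MSMF (multi-sensor matched filter).**  A strain template — the
duration-normalized, unit-energy average of the first five conservatively
detected loading bumps — is slid over the strain channel and the Pearson
correlation recorded at every alignment (`msmf_trace()`), giving values in
[−1, 1].  The trace is anchored at the *start* of the comparison window:
the template begins at a loading onset, so a similarity peak sits at the
stride's IC regardless of how long the loading phase is.  (Anchoring at
the window centre breaks down for slow conditions, e.g. stair walking,
where the bump centre sits more than the 0.5 s search window away from
IC.)  Each trace peak above the 50 % similarity threshold seeds a stride:
IC is the nearest confirmed positive strain crossing within ±0.5 s of the
peak, TC the first negative crossing after IC, PS the sub-sample-refined
maximum of the cane AP velocity between TC and the next IC, and EC the
first positive crossing after PS.  Strides failing the event order or the
0.4–3.0 s duration bounds are dropped with a logged reason.

**GPD (gyroscope peak detection).**  PS events are supra-threshold
excursion maxima of an AP velocity signal.  Gait minima are local minima
that dominate a ±0.15 s window with at least 5 °/s prominence and pass a
per-interval depth gate (25 % of the interval's deepest minimum, which
rejects shallow filter ripples on lobe shoulders).  Between two swing
peaks the minima appear in a fixed order — the boundary (IC/EC) valley
first, the next cycle's TC valley second — so TC is the *last* qualified
minimum before a peak and the boundary landmark the *deepest* after it.
The first stride's opening IC is the last qualified minimum preceding the
first TC.

The automatic threshold is half the 95th percentile of the positive
samples.  On a shank stream, stance activity is a small fraction of the
swing peak and the threshold cleanly separates the two.  On a *cane*
stream this separation is impossible for any threshold of this form: the
published control condition has a stance peak (156.4 °/s) larger than half
the swing peak (123 °/s), so stance lobes are also detected.  This is
harmless for the Difference-in-IC computation, because stance-lobe and
swing-lobe peaks share the same bracketing minima, and the IC landmark
list that `diff_ic()` consumes is the same either way.  A manually
supplied threshold always wins.

**Difference in IC.**  `diff_ic()` pairs MSMF and GPD initial-contact
landmarks greedily by time distance.  The function's default window is
half the *maximum* stride-duration bound (1.5 s), as generous as the
stride grammar allows; the pipeline calls it with half the *minimum*
bound (0.2 s), because the two algorithms' landmarks genuinely differ by
tens of milliseconds and a wide window lets a distant candidate be stolen
whenever one detection is missing.

**Synchronization.**  The cane and shank systems start independently;
participants stand still holding the cane off the ground before walking.
The cane's first positive strain crossing and the shank's first prominent
AP-velocity minimum mark the same instant, so their time difference is the
clock offset between the streams.

## The eight features

Per valid stride (IC, TC, PS, EC):

| feature | definition | units |
|---|---|---|
| `max_pv_swing` | max AP velocity on (TC, EC] | °/s |
| `max_pv_stance` | max AP velocity on [IC, TC] | °/s |
| `max_pv_time_wrt_tc` | time of the swing maximum after TC | ms |
| `swing_stance_ratio` | (EC − TC)/(TC − IC) | — |
| `max_strain` | max strain on [IC, TC] | counts |
| `max_strain_time_wrt_ic` | time of the strain maximum after IC | ms |
| `stride_length` | pendulum-model chord (below) | m |
| `diff_ic` | IC(MSMF) − IC(GPD) on the cane | ms |

The swing window is half-open, (TC, EC], so a maximum exactly at TC counts
once, in stance.  Stride length uses a pendulum model *defined by this
package* (published descriptions of the instrument report the feature
without fixing its computation):
the cane pivots about its planted tip, the swing sweep angle is the
trapezoidal integral of the AP velocity over (TC, EC], and the stride
length is the chord `2 L sin(θ/2)` for cane length `L`.  Negative sweeps
clamp to zero and are logged, not errors.  The shank analogues use the
same form with a configurable effective limb length (0.9 m) — explicitly a
validation convenience.

## The synthetic-data generator

No public recordings exist for this instrument, so the generator is a
first-class component: it emulates the per-stride waveform structure of
cane-assisted walking with *known* event times and parameters, at the
statistical operating point of each of the eleven published walking
conditions (control, plantar/dorsiflexion, uphill/downhill,
up/downstairs, fogged glasses, eyes closed, long/short cane).  Profile
fields that the published summaries fix — peak velocities, swing-stance
ratio, peak strain, stride length, the GPD IC lag (the negated
Difference-in-IC), ±2 inch cane lengths — carry those values.  Fields the
summaries do not fix are package choices, stated here once:

* **Phase durations.**  Mean cane stance 0.65 s for level-ground
  conditions and 0.90 s for stairs (stair walking is slower); swing
  follows from the published swing-stance ratio.  The peak-velocity and
  peak-strain timing of conditions whose summaries omit them scale the
  control values by the condition's phase durations.
* **Variance split.**  The published per-condition SDs are pooled; the
  generator splits each variance evenly between a between-participant and
  a within-participant level (`between_participant_sd_scale = 0.5`,
  configurable), which makes the repeated-measures structure
  non-degenerate.  Whether the printed SDs pool strides and participants
  is unknown, so the split is a parameter, not an assertion.
* **Cohort centring.**  Participant-level z-shifts are centred across the
  cohort, so a simulated cohort reproduces the published condition means
  exactly rather than drifting around them; stride-level draws stay
  independent.  Without centring, a 30-participant cohort mean of a
  high-variance feature such as peak strain (CV ≈ 0.5) wanders several
  percent from seed to seed, which says nothing about the pipeline being
  validated.  Centring only touches the subject *main* effects, which the
  within-subject ANOVA removes anyway; its error term (the
  subject-by-condition interaction) is untouched, and the empirical
  type-I error stays at the nominal 5 % (checked in the test suite over
  1000 null replicates).
* **Correlated draws.**  Swing- and stance-phase peak velocities share a
  correlation of 0.8 at both levels: a walker who swings the cane fast
  also moves it fast in stance.  Independent draws would make the
  invariant `v_stance < v_swing` bind on ~10 % of draws and visibly bias
  both means.
* **Truncation.**  Draws are truncated normals (±3 SD) clamped to
  physical bounds: durations positive, apex offsets inside their phase,
  stride length within the pendulum's reach, and a minimum strain-release
  time that grows gently with the loading peak (a heavier load releases
  more slowly).

The per-stride waveforms are smooth piecewise trigonometric shapes chosen
so that every drawn parameter is recoverable by the pipeline: a
quartic-sine strain bump whose zero-crossings are pinned at IC and TC and
whose apex is pinned in time and height; a sin² gyro stance lobe peaking
at `v_stance`; a swing complex that rises to `v_swing` exactly at
TC + `ps_offset`, falls along a cosine-power curve, and ends in a compact
symmetric dip whose minimum sits at EC + `gpd_ic_lag` — the landmark GPD
reads as the next IC.  The free shape parameters (fall exponent, rise
exponent, a gently tilted plateau for long strides, in the extreme a
uniform stretch of the cycle) are solved numerically so the sampled
swing-phase integral equals the pendulum sweep of the drawn stride
length; the stretch preserves the swing-stance ratio and all eight
features, only the (unpublished) cycle time changes.  Draws whose sweep
cannot be realized even by stretching (a slow swing with an extreme
stride length) are clamped to the largest achievable sweep, which the
truth records; `synth_stride()` with an explicit draw raises an error
instead.

Emitted channels are **band-limited with the package's own zero-phase
filters** before noise is added, and the strain knots and gyro swing apex
are pre-compensated against the full analysis chain (second filter pass
plus baseline correction), so that the pipeline-measured landmarks land on
the ground-truth times to within ~0.1–2 ms.  This is what makes
"recovered within one sample" a meaningful contract rather than an
accident of filter bias.  White noise (1 count strain, 1 °/s gyro by
default) is added last; the unloaded strain level is −2 counts.

What the generator deliberately does *not* emulate: accelerometer content
(zeros), turns, pauses, stair geometry, soft-tissue artifacts,
participant-specific waveform idiosyncrasies, or any correlation between
features beyond the swing/stance velocity pair.  Passing the recovery
tests therefore demonstrates that the pipeline is exact on signals whose
event grammar matches the model — it does not certify performance on real
recordings, where template drift, non-stationary baselines and missed
contacts are the dominant failure modes.

## Statistics

The per-subject unit entering the statistics is the subject's mean feature
over valid strides per condition (published analyses do not state the
aggregation level; stride-level tables remain available).  For each
feature, a one-way repeated-measures ANOVA partitions the subject ×
condition matrix into condition, subject and error sums of squares, with
`F = MS_condition / MS_error` on (k−1), (k−1)(n−1) degrees of freedom.
No sphericity correction is applied by default; a Greenhouse–Geisser flag
exists for sensitivity analysis.  Pairwise contrasts are paired two-sided
t tests with Bonferroni adjustment (raw p times the number of pairs,
capped at 1) at α = 0.05; zero-variance difference vectors are flagged
degenerate and never significant.  `normalize_to_control()` divides each
condition mean by the control mean per feature and stream, and
`make_report()` renders the per-feature "(mean ± sd)" table with `*`
(condition ≠ control) and `**` (non-control pair) annotations.

## Numerical choices and edge handling

* Filter edges: odd-reflection padding, three cutoff periods long, with
  the recursion anchored at the first sample's level; strides whose
  events fall within the recording's quiet lead-in/out are unaffected.
* Ties: equal trace peaks or velocity maxima resolve to the earliest
  sample; PS apexes are refined to sub-sample precision by quadratic
  interpolation (the flat-topped swing of a long stride otherwise
  quantizes to the sample grid).
* Degenerate inputs: constant strain warns and returns zeros; an empty
  supra-threshold set yields an empty event list, not an error;
  single-condition studies skip the ANOVA stage.
* Problem sizes: the bundled validation studies use 30 participants with
  40 strides per trial (20 for stairs), matching the published cohort
  size; a full single-condition study runs in well under a minute.

## Known limitations

* The pendulum stride-length model is this package's definition; absolute
  stride lengths from real data inherit its assumptions (planted-tip
  pivot, sagittal-plane sweep).
* The automatic GPD threshold is principled for shank-like signals only;
  cane streams need either the landmark-robust pairing described above or
  a manual threshold.
* Recovery tolerances are demonstrated on the generator's signal family;
  real strain baselines that drift within a trial would need a windowed
  baseline correction that the package does not currently provide.
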