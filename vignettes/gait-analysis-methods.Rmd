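---
title: "Shank-gyroscope gait analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shank-gyroscope gait analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vestigait)
```

## The measurement model

During straight walking, a gyroscope strapped to the mid-shank sees almost
all of its rotation about the medio-lateral (pitch) axis. One stride of the
pitch angular-velocity signal has a stereotyped shape: a near-zero plateau
while the foot is flat on the ground (mid-stance), a sharp negative trough
as the shank rotates backward over the forefoot at toe-off, a large positive
peak as the shank swings forward (mid-swing), a second, shallower negative
trough at heel strike, and a return to the plateau. `vestigait` reduces each
stride to the four events (toe-off, mid-swing, heel strike, mid-stance) and
the eight derived parameters: maximum and minimum pitch NAV, the up-slope
(toe-off to mid-swing secant) and down-slope (mid-swing to heel-strike
secant), stride/swing/stance times and the stance-to-stride ratio.

"NAV" (normalized angular velocity) covers two distinct quantities, and
keeping them apart is the pivotal interpretive decision of this package:

* **Axis shares** (`axis_share()`): per sample,
  $\mathrm{share}_a = |g_a - o_a| \,/\, \sum_{b\in\{x,y,z\}} |g_b - o_b|$,
  where $o$ is the stationary zero offset. Absolute deviations are used so
  the shares are bounded in $[0,1]$ and sum to one; the raw ratio of signed
  angular velocities would be unbounded and singular whenever the components
  cancel, which is incompatible with shares being displayed on a bounded
  positive scale. Samples whose total absolute angular velocity is below
  1 deg/s correspond to an effectively stationary shank and are reported as
  missing. The walk-level summary is the median share per axis over the
  walking segment.
* **Pitch NAV** (`pitch_nav()`): the offset-corrected pitch channel
  $g_z - o_z$ in deg/s. All gait parameters are computed on this signal;
  amplitudes of hundreds of deg/s are physiological for the mid-swing shank
  and are incompatible with a ratio scale, which is why the two readings
  coexist.

Timing definitions are chosen so they are identities, not approximations:
stride time is toe-off to next toe-off, stance time is heel strike to next
toe-off, swing is their difference, and the ratio is
$100 \times \mathrm{stance}/\mathrm{stride}$. Defining the stride on
toe-off anchors makes `stride = swing + stance` hold for every emitted
cycle by construction; for steady gait the averages are unaffected by the
choice of anchor event.

## The synthetic walk generator

No public recordings accompany the study this pipeline targets, so the
package ships a generator (`simulate_walk()`) whose defaults *are* the study
conditions: an 88.8 m corridor walked one way at 1.11 m/s (controls) or
0.84 m/s (vestibular-neuritis patients), sampled at 50 Hz, with presets
calibrated to the published group means (`gait_reference_values()`):
controls at stride 0.98 s, peak 368.6 deg/s, trough −172.3 deg/s; left- and
right-lesion patient columns analogously. The two legs are phase-opposed
(the right leg is delayed by half a stride). Each recording carries a 5 s
stationary lead-in with constant per-axis offsets of (2, −3, 1.5) deg/s —
deliberately non-zero so the calibration path does real work — a 2-sample
500 deg/s synchronization spike such as shaking the sensors produces, the
walking segment, and a stationary tail.

Free parameters the publication does not pin down were fixed once, on
physiological grounds:

* **Heel-strike trough** `a_heelstrike = 0.85 * a_toeoff`, keeping toe-off
  the global cycle minimum as its definition requires.
* **Stride-to-stride variability**: log-normal multiplicative jitter
  (mean 1) on durations and amplitudes, which preserves signs and
  positivity by construction; defaults CV 0.03 (durations) and 0.05
  (amplitudes), typical stride-to-stride values for steady adult gait.
* **Sensor noise**: additive white Gaussian, SD 5 deg/s.
* **Roll/yaw channels**: scaled (fraction 0.3), independently
  amplitude-jittered copies of the pitch waveform plus noise, so pitch
  dominates the axis shares as it does on a real shank.
* **Contralateral leg of a patient walk**: a 50/50 interpolation between the
  lesion-side and control templates; the study reports asymmetry but no
  contralateral template.
* All randomness flows from one integer seed; per-leg and per-subject
  sub-seeds are derived deterministically.

### Grid alignment and what "calibrated" can mean

Event times inside each stride template are snapped to the 20 ms sampling
grid. A sharp off-grid trough sampled at 50 Hz can miss its true amplitude
by more than 10%, so snapping is what makes the sampled extrema equal the
preset amplitudes exactly. The price is quantization: segment durations are
realized to the nearest sample, so e.g. the realized control up-slope is
3005 deg/s² for a requested 2968.7 (+1.2%). `make_cycle_template()` returns
the realized parameter set alongside the requested one, and recovery tests
compare detection against the realized values (the ground truth of the
emitted signal), while preset-level checks compare against the published
means at the tolerance the quantization bound allows.

The published parameter table is itself over-determined: the amplitudes and
slopes imply a trough-to-trough swing span of about 0.354 s for controls,
while the printed swing time is 0.389 s, and forcing agreement would
require a heel-strike trough deeper than the toe-off trough, contradicting
the definition of toe-off as the cycle minimum. The template therefore
honors event *timings* (the heel-strike trough sits exactly one swing time
after toe-off), the amplitudes, and the up-slope segment; the descent
leaves the peak at the requested down-slope and eases into the trough with
a cubic Hermite arc (cosine easing, 40 ms, is used at the plateau
transitions). The realized peak-to-heel-strike secant is consequently
shallower than the published down-slope (about −2575 vs −3003 deg/s² for
controls), and down-slope recovery is validated against the realized
secant, not the published value. Every other parameter — amplitudes,
up-slope, stride, swing, stance, ratio, velocity, cadence — round-trips
within 2–3%.

What passing tests on this generator do **not** show: real pitch signals
have subject-specific trough shapes, double-support oscillations after heel
strike, turning artifacts, soft-tissue resonance and slow baseline drift,
none of which are emulated. The generator validates the *pipeline's*
correctness on signals with the assumed structure, not the clinical
validity of the parameters.

## Event detection

Mid-swing peaks are local maxima that clear both a height and a topographic
prominence threshold — each 0.4 times the 90th percentile of the positive
signal values — separated by more than 0.5 s (taller peaks win). Height and
prominence are required jointly: low noise bumps on the mid-stance plateau
sit between two deep troughs and are therefore topographically prominent,
while shoulders of genuine peaks are tall but not prominent. Prominence is
computed with segment boundaries acting as cols, so edge bumps are not
inflated by one-sided troughs.

Within each inter-peak span: the toe-off trough is the signal minimum
between the preceding inter-peak midpoint and the peak (starting at the
midpoint avoids capturing the previous cycle's heel-strike trough); the
heel strike is the first local minimum after the peak whose depth reaches
within 15% (of the peak-to-minimum range) of the window minimum — a plain
"first local minimum" is fragile under sensor noise near the flattening
descent; the mid-stance point minimizes \|signal\| between heel strike and
the next toe-off. Cycles whose events come out unordered, or whose toe-off
is not the cycle minimum, are flagged and skipped with a logged reason —
never imputed — and `n_strides` counts only valid cycles.

On noise-free, zero-variability simulations every detected event time
agrees with the generator's analytic event time to within one sample
(20 ms).

## Spectral cadence estimation

The walking segment (first to last mid-swing peak, padded by one mean
stride each side) is mean-removed, Hann-windowed, and transformed with a
single full-segment periodogram; walks last 60–110 s, the quantity of
interest is peak location rather than estimator variance, and a 10 s
minimum segment guarantees 0.1 Hz resolution or better. Power is normalized
to sum to one over the 0.3–6 Hz gait band (below 0.3 Hz is drift, above
6 Hz noise for normal walking). The three dominant peaks are local maxima
with prominence at least 5% of the band maximum, selected by power and
reported in ascending frequency as `f1 < f2 < f3`; for steady gait `f1` is
the cadence (the reciprocal of the stride time, within one frequency bin on
zero-variability simulations) and `f2`, `f3` are its harmonics. If fewer
than three peaks qualify the remainder are `NA`. The elevated,
non-harmonic second peak reported for patients in the source study has no
stated mechanism and no generator preset claims to reproduce it.

## Group statistics

The reporting workflow mirrors the SPSS conventions of clinical gait
studies. Per parameter: a Lilliefors-corrected Kolmogorov–Smirnov check per
group routes to one-way ANOVA (all groups normal at $\alpha = 0.05$) or
Kruskal–Wallis; a Brown–Forsythe (median-centred Levene) decision routes
post-hoc pairwise comparisons to Fisher's LSD (pooled variance, unadjusted)
or Dunnett's T3 (Welch statistics referred to the studentized maximum
modulus, computed here by direct numerical integration of its mixture
representation, as no installed package provides it). Stance time and the
stance ratio are compared with pairwise Mann–Whitney U tests under
Bonferroni correction with family size equal to the number of pairs. The
parameter-to-procedure routing is frozen (`default_routing()`) rather than
re-decided per dataset, with an override argument. The Mann–Whitney p-value
is exact by enumeration for combined samples up to 20 without ties (and is
validated against a brute-force permutation oracle in the tests), and a
tie-corrected normal approximation otherwise. The Lilliefors implementation
requires at least five observations, so groups of three or four default to
the parametric branch, recorded as unassessed normality.

Each simulated walk stands in for one subject, matching the study design
(10 controls vs 5 + 5 patients); patient rows use the lesion-side leg and
control rows the left leg, following the left-leg analysis perspective.

## Numerical choices and degenerate inputs

* Sampling is fixed at 50 Hz; uniform files at other rates are linearly
  resampled with a warning, sub-microsecond timestamp jitter is re-gridded
  silently, anything worse is rejected with the offending row.
* Sync detection thresholds the maximum inter-sample change across axes at
  150 deg/s per sample — several times the largest walking-induced change at
  50 Hz, far below a deliberate shake.
* Offset windows must span ≥ 1 s and be stationary (per-axis SD below
  10 deg/s).
* Identical-group inputs yield F = 0, p = 1 (ANOVA) and H = 0, p = 1
  (Kruskal–Wallis on full ties); zero-variance pairs give p = 1 in the
  post-hoc procedures rather than NaN.
* The cycle ensemble (`cycle_ensemble()`, 101 points by default) linearly
  interpolates onto the normalized stride, which can clip the sharp
  mid-swing peak by up to (max slope) × (half a phase step) — about 2% at
  the default resolution; tests assert that derivable bound.
* Validation problem sizes — 25–70 strides per simulated leg, cohorts of
  14 subjects, 200 null cohorts for the type-I calibration — keep the whole
  suite under ten seconds while leaving every estimate's Monte-Carlo error
  well inside the asserted tolerances.

## Known limitations

* One sensor per shank: step width, double support, joint angles and
  centre-of-mass trajectories are out of reach by design.
* Only offset zeroing is implemented; scale calibration against a reference
  inertial system is not reproducible from the published description.
* The printed stance-ratio SDs of the calibration table appear to be on the
  fraction scale while the means are percentages; values are preserved as
  printed and not reconciled.
* Between-group p-values of the source study are not reproducible without
  its raw per-subject data; the statistics module is validated on its own
  distributional properties (oracle equivalence, F = t², type-I error
  within binomial tolerance) instead.
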