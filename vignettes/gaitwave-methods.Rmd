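---
title: "Methods: single lumbar-accelerometer gait analysis and its statistical validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single lumbar-accelerometer gait analysis and its statistical validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## What this package does and for whom

`gaitwave` extracts clinically interpretable gait features -- stride, step,
stance, swing and double-support times, stride and step length, gait speed,
cadence, and their asymmetry and variability -- from a single triaxial
accelerometer worn on the lower back (around the L5 vertebra), and provides
the statistical toolkit used to validate such features in clinical movement
studies: agreement against a reference system, test-retest reliability,
criterion validity against a clinician's ordinal gait-impairment rating
(0-4), and discrimination between medication On and Off states in Parkinson
disease. A built-in simulator generates walks with known ground truth so the
whole chain can be verified end to end without clinical data.

The intended user is a movement-science or digital-biomarker researcher with
bout-level recordings of supervised walking tasks (for example, a 2-minute
back-and-forth walk over a 10-m track sampled at 128 Hz) plus a per-visit
clinical metadata table.

## Signal model and conventions

An accelerometer measures specific force: at rest the vertical channel reads
+1 g. `orient_vertical()` estimates the gravity direction as the unit vector
of the mean specific force over the recording (equivalent to a 0.25 Hz
low-pass for a 2-minute quiet walking task, during which lumbar posture is
stable), requires its magnitude to be within 30% of standard gravity
(otherwise the device was not worn or the units are wrong), projects the
triaxial signal onto it, and removes the mean. Because the projection uses
the recording's own gravity vector, the output is invariant under any fixed
rotation of the device on the body -- there is no need to know how the unit
was mounted.

The extracted series `a_v` is signed so that **positive acceleration points
down** (along gravity). With the body's centre of mass (CoM) at its lowest
around each initial contact -- the inverted-pendulum picture of single
stance, where the CoM vaults over the stance leg and dips during
double support -- this sign convention makes the minima of the smoothed
vertical acceleration line up with initial contacts, which is what the event
detector exploits.

Units are canonicalised to m/s^2 on entry (`convert_units()`; device exports
are typically in g). Time is seconds from the start of the recording;
wall-clock stamps are converted on read.

## Gait event detection

`detect_gait_events()` implements a continuous-wavelet differentiation
scheme on the integrated vertical acceleration:

1. Band-pass `a_v` to the gait band (default 0.25-3 Hz, zero-phase
   Butterworth via forward-backward filtering so event timing is never
   phase-shifted). This filtered copy is used *only* for event detection;
   displacement integration (below) works on the unfiltered series because
   aggressive band-passing distorts displacement amplitude.
2. Integrate over time (cumulative trapezoid, mean removed first to bound
   drift over a 2-minute bout).
3. Differentiate with a first-derivative-of-Gaussian wavelet at the IC scale
   (`fs / f_step` samples, Gaussian sigma a quarter of that, i.e. a quarter
   step period). Local **minima** of this series are initial contacts.
4. Re-localise each IC at a finer scale (0.35 of the IC scale). The heavy
   first-pass smoothing is what makes detection robust, but it averages the
   timing of adjacent steps and thereby flattens genuine step-time
   asymmetry; the fine pass restores it. With the two-pass design the
   detector recovers a programmed 40 ms step-time asymmetry to within about
   one sample at 128 Hz while keeping single-pass robustness.
5. Differentiate again at twice the scale; local **maxima** are final
   contacts. For the smooth CoM model the jerk maximum falls a quarter
   step-period after each initial contact, implying roughly a quarter of the
   stride spent in double support -- physiologically sensible for
   comfortable-pace walking.
6. Keep at most one FC strictly inside each IC-to-IC interval (the strongest
   candidate), drop events within the kernel edge region, and assign
   alternating pseudo-sides A/B to successive ICs. A single lumbar sensor
   cannot identify anatomical left and right; alternation is sufficient for
   asymmetry features, which is all the downstream code needs.

The wavelet scale is tied to the dominant step frequency,
estimated by `dominant_step_frequency()` as the peak of the periodogram in
0.5-3 Hz after smoothing to about 0.1 Hz resolution; the peak must exceed
10 times the median in-band smoothed power, otherwise the bout is judged to
contain no gait (the smoothing step is what prevents a single large noise
bin in a broadband spectrum from posing as a periodicity). Peak picking uses
a minimum separation of a quarter step period and a topographic-prominence
floor of 20% of the series' median absolute deviation to suppress noise
doublets. All of these constants are exposed in `event_config()`.

Two detector symmetries are worth noting (and are property-tested): the
wavelet differentiation operator is exactly antisymmetric under time
reversal, so on a reversed recording the roles of the two extremum families
swap -- reflected initial contacts are recovered in place (the acceleration
minima are symmetric about each contact), while the final-contact family
moves to the mirror phase a half step away; and the whole pipeline is
invariant to positive amplitude scaling and time translation.

## Strides, quality control, and spatial measures

`assemble_strides()` forms one candidate stride per IC with two following
ICs (`ic0`, contralateral `ic1`, ipsilateral `ic2`) and reads the temporal
measures directly off the event sequence: stance ends at the FC between
`ic1` and `ic2`; double support sums the two FC lags. Stride time is
computed as the sum of its two step times so the identity
`stride = step0 + step1` holds bitwise, as does `stance + swing = stride`.

Quality control marks strides invalid rather than deleting them, with a
reason: missing FC, stride time outside 0.4-2.25 s (covering pathological
through brisk gait), stance fraction outside 0.4-0.8, or a turn. The
10-m track forces a turnaround roughly every 20-30 steps; with no gyroscope
in scope, turns are flagged purely temporally as strides exceeding 1.4 times
the bout median stride time. Only valid strides enter aggregation.

Stride length uses the inverted-pendulum model: a pendulum of length `l`
pivoting over the stance foot whose pivot height changes by `h` subtends a
step of `sqrt(2 l h - h^2)`, and the stride is twice that. `l` defaults to
0.53 x body height (a standard anthropometric ratio for lumbar sensor
height) and is configurable. Step length is `stride_length / 2`: per-side
step lengths are not resolvable from a lumbar device, so the symmetric split
is the convention.

The vertical excursion `h` is obtained per stride by double-integrating the
**raw** vertical acceleration over `[ic0, ic2]` with drift control at every
stage:

* a least-squares line is removed from the windowed acceleration. This
  kills constant bias and linear sensor drift exactly (a pure ramp
  integrates to zero excursion), and is phase-neutral for stride-periodic
  content because a cosine anchored at initial contact is orthogonal to a
  linear trend over whole periods;
* endpoint-anchored lines (through the first and last sample) are removed
  from the velocity and the position series. Least-squares detrending is
  *not* phase-neutral for the sine-phased velocity -- over full periods a
  sine has a nonzero projection on a linear trend, and removing it inflates
  the apparent amplitude by about 20% -- whereas the body returns to the
  same posture at consecutive ipsilateral contacts, so matching like-phase
  endpoints distorts nothing.

`h` is the peak-to-peak range of the detrended position. On noise-free
closed-form input this recovers the programmed excursion to about 3%, and
stride length (which scales as the square root of `h`) to well under 2%.
Excursions exceeding `l` mark the stride invalid rather than erroring.

## Bout aggregation and feature definitions

Features are aggregated per bout (subject-visit) as the **median** over
valid strides, requiring at least 3. Asymmetry and variability are not given
a formula in much of the applied literature, so the package fixes explicit,
configurable definitions and documents them as a divergence risk when
comparing against other systems:

* `asymmetry`: absolute difference of the pseudo-side medians, in the
  feature's units (mean-based variant selectable);
* `variability`: within-bout sample standard deviation (coefficient of
  variation selectable).

The one-device roster is the lumbar-derivable set: the five temporal
measures, stride/step length, gait speed, cadence, asymmetries of step,
stance and swing time, and variabilities of the temporal and spatial
measures. Three- and six-device rosters (lower-limb pitch features, trunk
and upper-limb features) exist only as named selections for feature tables
ingested from an external multi-sensor system -- the package never computes
them.

## The statistical validation harness

**Agreement and reliability.** ICC(2,1) -- two-way random effects, absolute
agreement, single measurement -- computed from the two-way mean-squares
decomposition, with F-based confidence bounds using a Satterthwaite
approximation for the denominator degrees of freedom. Against a brute-force
variance-components oracle built on `aov()` the implementation agrees to
1e-10. Categories follow the standard benchmarks: at or below 0.4 poor,
to 0.59 moderate, to 0.74 good, 0.75 and above excellent. Bland-Altman
analysis reports the mean difference and 95% limits of agreement
(mean +/- 1.96 SD of the paired differences).

**Group differences.** Kruskal-Wallis (tie-corrected, chi-square reference)
across score groups via `stats::kruskal.test`; Conover-Iman t statistics on
the pooled mid-ranks for post-hoc pairs (implemented here -- no installed
package provides it), with Benjamini-Hochberg FDR adjustment
(`stats::p.adjust`) for multiplicity.

**Criterion validity.** Features are pruned for collinearity (greedy
removal while any pair has |r| at or above 0.9 -- the member with the higher
mean absolute correlation to the rest is dropped, ties broken by column
order), standardized to zero mean and unit variance, and entered together
with age, gender, visit, BMI and years since first symptoms as fixed effects
in a linear mixed model of the clinician score with a per-participant random
intercept, fitted by maximum likelihood (`nlme::lme`; ML rather than REML so
AIC comparisons across fixed-effect sets are valid). Fixed effects are
selected by bidirectional stepwise AIC from the full model
(`MASS::stepAIC`); the random intercept is never dropped. Per-term Type-III
Wald chi-square tests (`b' V^-1 b`, reducing to `(estimate/SE)^2` for scalar
terms) are computed directly from the coefficient covariance and
cross-checked against `car::Anova` in the test suite. The ordinal 0-4 score
is treated as numeric in a linear model, mirroring standard practice in this
literature; ordinal-response models are out of scope.

Predictive performance is assessed by leave-one-subject-out cross-validation:
each subject's observations are predicted from a model refitted without that
subject, using fixed effects only (a new subject's random intercept is
unknown). The report is the RMSE over held-out predictions plus the marginal
R-squared of the full fit, `var(Xb) / (var(Xb) + s2_intercept + s2_residual)`.
Two design points deserve emphasis:

* *Selection happens once, on the full data, before cross-validation* --
  each fold refits the selected model rather than re-running selection.
  This mirrors the common applied workflow but lets the held-out subject
  influence which terms were selected; it is flagged here as a known,
  deliberate leakage risk of that workflow. What the folds themselves never
  leak is data: perturbing a held-out subject's response cannot change its
  own fold's predictions, and this is property-tested.
* *The expected LOSO error for an unseen subject is
  sqrt(s2_intercept + s2_residual)*, not the residual SD alone, because the
  subject's random intercept is part of what cannot be predicted from fixed
  effects. The calibration tests use that target.

**Discriminative validity.** Held-out predicted scores are paired within
subject across medication states and compared with the Wilcoxon signed-rank
test: zero differences excluded, mid-ranks for ties, and -- for up to 25
non-zero pairs -- an exact p value from the full distribution of the signed
rank sum over all sign assignments, computed by dynamic programming on
doubled mid-ranks so that ties are handled exactly (a shift of one unit in
six subjects, all tied in magnitude, has one-sided p of exactly 1/64).
Beyond 25 pairs the normal approximation with continuity correction is used.

A note on one invariant that was *not* adopted: Benjamini-Hochberg
adjustment is not idempotent (adjusted values of `(0.1, 0.5)` are
`(0.2, 0.5)`, which re-adjust to `(0.4, 0.5)`), so the suite tests
permutation invariance and rank monotonicity instead.

## The simulator: what it emulates and what it does not

`simulate_walk()` produces the raw signal of a steady walk: one cosine arc
of CoM height per step (minimum at initial contact, peak-to-peak excursion
`h0`, defaults 0.02-0.05 m -- physiological lumbar excursions), per-step
durations alternating around `stride_time / 2` by the programmed step-time
asymmetry, gravity, a decaying 12 Hz impact transient at each initial
contact (amplitude configurable; it gives the detector the sharp features
real heel strikes produce), white noise (`walk_noise_sd()` converts a target
SNR in dB to a noise level), and a fixed random device rotation so that
orientation recovery is always exercised. An initial contact is declared at
every step boundary inside the recording, including the final one; the
trajectory's last partial step runs smoothly to the end of the signal so
that no undeclared contact feature exists for the detector to find.
Ground-truth final contacts are placed a quarter step-period after each
initial contact, which is exactly where the smooth model's jerk peaks.

What the simulator deliberately does not model: turning (straight-line gait
only -- the turn-flagging QC rule is exercised with synthetic event
sequences instead), freezing of gait, dyskinesia, postural transitions,
stair gait, soft-tissue resonance, and any free-living content. Passing the
recovery tests therefore demonstrates the internal consistency and numerical
correctness of the pipeline under its own assumptions, not clinical accuracy
on real recordings -- the latter requires reference instrumentation.

`simulate_cohort()` generates the longitudinal table structure of a clinical
study in two directions. `"feature_response"` mirrors the clinical data
generating intuition: a per-subject baseline score drawn from the score
frequency profile of a mild-to-moderate Parkinson cohort (17:27:18:6 for
scores 0-3), one On and one Off visit in randomized order with an expected
On-to-Off score increase of 0.4, covariates drawn at cohort-plausible values
(age 68 +/- 8, BMI 29 +/- 7, symptom duration about 6 years), and each
feature equal to intercept + slope x score + subject intercept + noise (for
example gait speed 1.2 m/s at score 0 declining 0.2 m/s per point).
`"score_response"` reverses the direction -- standardized features, score =
X beta + subject intercept + noise -- which is the direction in which
mixed-model estimation, marginal R-squared and LOSO error have exact known
targets; the calibration tests use beta = (-0.8, 0.6) with intercept and
residual variances of 0.5 each, i.e. variance components 1.0/0.5/0.5 and a
plug-in marginal R-squared of 0.5.

## Numerical choices, problem sizes, and determinism

Simulation-based checks in the test suite use 2-minute (or, where a shorter
bout suffices, 45-90 s) walks at 128 Hz and 20 dB SNR across stride times
0.8-1.6 s; cohort calibration uses 200 subjects with two visits (150 for the
replicate-averaged plug-in check, three and five replicates respectively for
quantities whose single-draw sampling spread is comparable to the tolerance
being verified); null-calibration of the rank tests uses 2000 replicates at
group sizes of 20, where the exact attained size of both tests is within a
point of the nominal 5%. These sizes were chosen so each property is tested
where its expected behaviour is sharp.

Everything downstream of a seed is deterministic: the generators are pure
functions of (parameters, seed) and restore the caller's RNG state; the
analysis chain contains no randomness at all, so identical inputs give
byte-identical output files. The command-line wrapper stamps each output
directory with the seed and a configuration hash.

Degenerate inputs are handled explicitly rather than silently: constant
signals, absent gait periodicity, too few valid strides, empty pseudo-sides,
constant feature columns, incomplete ICC tables, all-zero difference
vectors, and cohorts without repeated measures (where the mixed model
degrades to a fixed-effects fit with a warning) all raise informative
conditions. Batch analyses (agreement/reliability across many features)
convert a degenerate feature into an NA row with a warning instead of
aborting the run.

## Known limitations

* The wavelet scales, band edges, QC bounds and pruning threshold are
  field-standard defaults, config-exposed; none were fitted to data.
* Asymmetry and variability definitions vary across the literature; results
  for these features are comparable across systems only up to that choice.
* The inverted-pendulum model underestimates stride length at the extremes
  of excursion and the symmetric step-length split hides lateralised
  deficits; both are inherent to single-lumbar-sensor methods, along with
  the distal location of the sensor relative to the feet and the error in
  estimating vertical displacement from acceleration.
* Treating the 0-4 ordinal score as numeric, selecting terms before
  cross-validation, and using a single random intercept (rather than a
  richer within-subject covariance structure) are deliberate simplifications
  recorded above.
* Free-living gait (bout detection, turning, non-straight walking) is out of
  scope; the pipeline expects supervised straight-line bouts.
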