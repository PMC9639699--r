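---
title: "Methods: event detection, cleaning, and the asymptote time-course model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: event detection, cleaning, and the asymptote time-course model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ambientfocal)
```

## The scientific problem

When people freely view a scene, oculomotor behaviour reorganises over
seconds: early viewing is dominated by *ambient* processing — short
fixations linked by large saccades that survey scene layout — and later
viewing by *focal* processing — long fixations linked by small saccades
that scrutinise details. Gaze-contingent masking manipulates which part
of the visual field drives this process: a 5° *window* restricts input
to central vision, a 5° *scotoma* removes it, and an unmasked display
serves as control. This package implements the quantitative machinery
such experiments need: event detection from raw gaze samples, a fully
accounted cleaning cascade, 500-ms time-course binning, a nonlinear
asymptote model with time-to-asymptote estimation, ambient/focal
classification, and tidy per-participant exports. Inferential statistics
(repeated-measures ANOVA, sphericity corrections, planned contrasts) are
deliberately out of scope: the summary tables are the exact input any
standard stats package expects, and reimplementing those tests adds
nothing specific to this design.

## Geometry

Screens are described by their pixel resolution and angular radii
(defaults 1024 × 768 px, ±14.7° × ±11.2°, 71.5 cm viewing distance,
1000 Hz). Pixel-to-degree conversion is linear per axis, i.e. a
small-angle approximation of the true tangent geometry; at 14.7°
eccentricity the discrepancy is below 2% and it buys exact
invertibility. Angular distance is planar Euclidean distance in degree
space, consistent with that approximation.

## Event detection

The saccade parser mirrors the EyeLink online parser's published
thresholds: a candidate begins where gaze speed exceeds 30°/s **or**
absolute acceleration exceeds 8000°/s², with the trigger sustained for
at least 4 ms, and ends at the first sample where speed *and*
acceleration are both below threshold. Completed candidates must move
the eye by more than 0.1° start-to-end; the deflection test is applied
as a post-hoc filter rather than as a gate on candidacy (the published
description lists the criteria without a boolean; the OR-at-onset
reading matches how online parsers behave, and both choices are
parameters).

Kinematics come from a 3-ms boxcar smoothing of positions followed by
two-point central differences (speed), and central differences of speed
(acceleration), with replicated endpoints. These are the simplest
estimators consistent with the thresholds; the smoothing width is a
parameter. Two consequences are worth knowing:

- **Boundary anticipation.** Smoothing spreads a position step into
  neighbouring samples and the acceleration trigger fires on the rise of
  the speed curve, so detected onsets/offsets can lead the kinematic
  boundary by up to ~3 ms (smoothing half-width plus one central-
  difference step). The detector's unit tests pin this convention down.
- **Blinks are opaque.** Samples with missing or zero pupil yield
  missing kinematics. Missing values neither trigger a saccade nor
  terminate one: a candidate that runs into a blink spans it and is then
  discarded by the blink-overlap rule. Fixations are the complement of
  saccades and blinks, so events always partition the trial — a
  property the tests assert exactly.

All intervals are half-open `[onset, offset)` in integer milliseconds.
Saccade amplitude is measured from the onset sample to the first quiet
(landing) sample, not peak excursion.

## The cleaning cascade

Four rules run in a fixed order: (1) events starting before scene
onset; (2) events whose interval comes within 100 ms of a blink
(overlap counts as gap zero; the window is symmetric); (3) fixations
shorter than 80 ms or longer than 1000 ms — the bounds themselves are
kept, since the exclusion wording is strict; (4) trials with total blink
time at or above 4 s (20% of a 20-s trial; the bound itself is
excluded). Order matters for attribution — an event violating two rules
is counted by the first — and a test fixes the order with a fixture
where reordering changes the per-stage tallies.

Every removed fixation/saccade lands in a quarantine table with its
reason, so `kept + removed = input` holds at every stage. Stage
percentages are reported against the pre-cleaning fixation + saccade
count; the trial rule against the trial count; the total is the sum of
stage percentages. That convention is the one under which the stage
figures of a typical free-viewing data set add up to its overall
exclusion figure.

## Time-course binning and the asymptote model

Events are assigned to 500-ms bins by onset (half-open edges). Within
each bin, participant means are computed first and the across-
participant mean carries a t-based 95% CI; bins with fewer than two
participants are flagged. The CI unit (participants) is a choice: the
error bars in this literature are drawn over a fixed participant
sample, but event- or trial-level units would be defensible too, which
is why the aggregation is isolated in `bin_events()`.

The model `mean ≈ b · exp(a / t)` is fitted by unweighted nonlinear
least squares over bin means (Levenberg–Marquardt, parameter tolerance
1e-10), initialised from the mean of the last three bins (`b0`) and the
slope of an ordinary regression of `log(mean)` on `1/t` (`a0`). On
noiseless model data the NLS solution coincides with that log-linear
OLS solution, which the tests use as an independent oracle. `b`'s
confidence interval is t-based from the estimator covariance.
Non-convergence is reported, never silently patched, and downstream
operations refuse unconverged fits. Saccade-amplitude fits skip the
first two bins: amplitudes first rise to a peak near 1.5 s before
declining, and the single-exponential cannot represent that initial
ramp.

**Time labels.** A bin's time `t` is its end time by default (bin 3 is
1.5 s), the convention under which reach times land on the familiar
0.5-s lattice. Midpoint labelling is available via
`bin_events(..., t_label = "midpoint")` and matters for simulation
work (below).

**Time-to-asymptote** is the first bin (after any skipped bins) whose
95% CI contains the fitted `b`; no persistence beyond that bin is
required, and "no bin qualifies" is an `NA`, not an error. Note that
this quantity depends on CI width and therefore on sample size and
between-participant variance, not only on the curve.

## Classification and slicing

A fixation inherits the amplitude of the saccade whose offset abuts its
onset. Amplitudes strictly above 5° label it ambient, at or below 5°
focal (equality has essentially measure zero; the tie rule is fixed and
tested), and fixations with no abutting saccade — the first of a trial,
or one whose preceding saccade was cleaned away — stay unclassified.
Interval membership (early 0–2 s, late 6–8 s) is decided by onset, so
an event straddling a boundary counts with the interval it started in.
Aggregation always takes participant cell means first and unweighted
grand means second; empty cells appear explicitly with zero events.

## The synthetic scanpath generator

The simulator exists so that every stage is testable against known
ground truth. It is an alternating fixation–saccade renewal process:

- **Fixation durations** are Gamma (shape 6) with mean
  `b_fd · exp(a_fd / max(t, 0.25))`, clocked by the fixation's *start*
  time in seconds; the 0.25-s floor avoids the `t → 0` singularity.
- **Saccade amplitudes** are log-normal (log-sd 0.35) with *median* on
  the condition curve `b_sa · exp(a_sa / max(t, 0.25))`, drawn
  mask-consistently by rejection: within 5° of gaze in the central
  condition, beyond 5° in the peripheral one, unconstrained in control
  (after 100 rejections the constraint is dropped for that saccade).
  Directions are uniform, re-drawn to keep the endpoint on screen, with
  amplitude clipped toward the screen edge as a last resort.
- **Saccade kinematics** are rendered with a raised-cosine speed
  profile; the duration rule
  `D = max(4, min(21 + 2.2·A, 44·A))` ms is main-sequence-flavoured and
  guarantees the peak speed `2A/D` exceeds the 30°/s threshold for any
  amplitude ≥ 0.3°.
- **Blinks** arrive as a Poisson process (0.12/s, mean 150 ms), zero the
  pupil, and mask position. They are carved out of the event schedule,
  splitting fixations where needed, so the ground truth keeps the
  partition property.
- **Noise** is Gaussian on fixation samples (sd 0.03°).

Default curve parameters are the fitted values typical of this paradigm
(fixation-duration asymptotes 283.5/311.4/321.2 ms and amplitude
asymptotes 3.5/8.1/5.4° for central/peripheral/control); acceleration
defaults are set so the curves approach asymptote between roughly 3.5
and 6 s. The design defaults emulate the full experiment: 42
participants × 3 conditions × 30 trials of 20 s at 1000 Hz, scene types
alternating natural/urban 15/15 within each condition. Per-trial child
seeds derive from the master seed, so datasets are bit-reproducible and
single trials can be regenerated in isolation. Rendering 1000-Hz
samples is optional (`render_samples`); the event schedule and blink
draws precede rendering noise in the random stream, so ground truth is
identical with or without rendering — which keeps multi-seed
experiments at event level fast.

### What the generator does and does not emulate

It reproduces the *mean structure* this analysis targets — the
time-course curves, mask-dependent amplitude distributions, blink
contamination, and the design counts. It does **not** emulate:
between-participant heterogeneity (all simulated participants share one
parameter set, so across-participant CIs are far narrower than in real
data and simulated reach times are correspondingly later);
image-driven gaze targeting or saliency; microsaccades,
post-saccadic oscillations or smooth pursuit; pupil dynamics beyond
blink dropout; off-screen gaze and whole-scene occlusion. Distribution
shapes (Gamma, log-normal) are field-standard conventions, not
estimates — passing recovery tests shows the pipeline is consistent for
data of this structure, not that real data has this structure.

### Estimating generator parameters back (consistency)

Two details matter when the pipeline's fit is compared against the
generator's own parameters, and both are estimator choices rather than
tuning:

1. **Clock alignment.** The generator clocks its curve by fixation
   start time, so a bin's realized mean corresponds to the curve near
   the bin's *midpoint*. Fitting end-labelled bins against start-clocked
   data systematically inflates `|a|`; the recovery experiment therefore
   uses midpoint labels. (For real data the end-label default stands:
   there the label is a reporting convention, not a model-consistency
   question.)
2. **Which events to fit.** Blink carving splits fixations into short
   pieces and the trial end right-censors the final fixation; the
   recovery estimator removes blink-adjacent events (the cleaning rule
   that exists for exactly this purpose) and censored final fixations,
   and drops the last two bins, where censoring depresses the means.
   The 80/1000-ms duration bounds are *not* applied there, because the
   generator draws durations without bounds and the truncation would
   bias `a`. For amplitudes, the generator's log-normal-median +
   mask-truncation construction means the binned *means* converge to a
   truncated-log-normal mean rather than to `b_sa` itself;
   `sim_amplitude_asymptote()` provides that closed-form target.

`recover_generator_parameters()` packages this experiment;
`signature_experiment()` checks the qualitative early/late and
condition-ordering signature. The shipped validation runs use 20 seeds
each, with the recovery experiment at a 10-participant variant of the
design and the signature experiment at the full 42 — sizes chosen so
the whole suite stays comfortably interactive on one core while the
Monte-Carlo error of the checked quantities remains far below the
tolerance bands.

## Numerical and degenerate-input conventions

- Timestamps are integer milliseconds; fractional input is rejected,
  not rounded (silent rounding hides sample-rate faults).
- Non-uniform sampling and overlapping input events are hard errors.
- Missing fields decode from `"."`, empty, or `NA`; pupil 0 counts as
  missing (blink), following EyeLink conventions.
- Event CSV output formats milliseconds as integers and degrees/pixels
  at 6 significant digits; a write–read round trip reproduces the table
  exactly after one normalisation pass.
- The fit requires at least 4 usable bins after skipping and strictly
  positive bin means (the exponential model is log-linearisable only
  then).
- `predict()` rejects non-positive times: the model is undefined at
  `t = 0` and the curve's domain is viewing time.

## Known limitations

Monocular only (binocular sources must be reduced upstream); no
microsaccade/glissade machinery — the 0.1° deflection floor and 4-ms
sustain are not meant to resolve them; the small-angle geometry slightly
compresses eccentric amplitudes relative to tangent geometry; and the
asymptote model is a single exponential — it cannot capture the initial
amplitude ramp (hence the skipped bins) and alternative families
(logistic, power law) are out of scope.
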