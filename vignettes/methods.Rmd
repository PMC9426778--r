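---
title: "Methods: quantifying whisker-eye coordination in maze navigation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying whisker-eye coordination in maze navigation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the measurement
model, the tunable parameters and why their defaults are what they are,
what the synthetic-data generator does and does not emulate, and the
numerical and design choices made where the design was genuinely open. It
states no empirical result that the test suite or the acceptance script do
not themselves compute.

## The measurement model

A session consists of self-paced trials in a plus maze, each annotated with
a fixed state sequence: quiet sitting at the end of a lane, backward
movement out of the lane, a cued left or right turn, forward movement into
the next lane, reward expectation, and licking. Two tracked modalities feed
the analysis:

**Whiskers.** One painted whisker per side is tracked at 200 Hz as a
luma-weighted centroid of hue-masked pixels (`hue_centroid()`); dropped
frames are filled by linear interpolation. Because a whisker sweeps an
approximately circular arc around its follicle, a single least-squares
circle is fitted to each whisker's positions for the whole session
(`fit_circle()`, algebraic Kåsa form) and positions become polar angles
about that circle. Angles are centered on the session median — the
"provisional zero", robust to slow setpoint drift — and expressed per trial
as a percentage of the trial's full range of deviation (0% = trial minimum,
100% = trial maximum, `normalize_whisker()`). Whisker asymmetry is
`w_R − w_L` of these normalized positions, signed toward the cued turn
(`w_R − w_L` for left turns, `w_L − w_R` for right turns): positive
asymmetry means "whiskers configured for the cued turn".

**Eyes.** Eight pupil-edge keypoints per eye at 100 Hz are fitted with a
direct least-squares ellipse (`fit_ellipse()`, Fitzgibbon constraint
`4ac − b² = 1`); the center and equivalent diameter are the pupil position
and size. Eye size in pixels varies across sessions, so position is
normalized by the eye itself: parabolas are fitted to the two eyelid
outlines, their two real intersections are the eye corners, and the segment
joining them is the eye width (`fit_eye_geometry()`). The pupil center is
projected onto this segment and expressed as a fraction of its length
(`normalize_pupil()`; 0 = nasal corner, 1 = temporal, not clamped). For
conjugate (two-eye) analyses both eyes are mapped onto one head-centered,
leftward-positive axis: the left eye's nasal→temporal axis already points
left, the right eye's is flipped. Pupil deviation is the two-eye mean
displacement from the session median, in % of eye width, optionally signed
toward the cued turn (`pupil_deviation()`).

**Saccades.** Pupil speed is the raw per-frame first difference of
normalized position (% eye width per frame). An event requires both eyes'
absolute speed to cross the threshold with the same head-centered sign
within ±1 frame; the event time is the frame of peak absolute mean speed in
the supra-threshold run, and the amplitude is the net two-eye mean
displacement across the run. Any train of events with inter-event intervals
below the refractory window is treated as a tracking artifact and discarded
in full (a `keep_first` flag retains the train's first event for
sensitivity analyses). Missing frames — e.g. ellipse fits dropped by
confidence gating (`fit_pupil_frames()`) during occlusions — can never seed
events.

**Prediction.** The backward epoch is divided into five equal
normalized-time bins. Per bin, two signed raw predictors are formed:
whisker asymmetry as raw `w_R − w_L` (positive precedes left turns) and eye
position as leftward-positive deviation. Single-variable performance is the
ROC/AUC of "predict left when the value exceeds a threshold", swept over
all observed values; the trapezoid AUC equals the Mann-Whitney `U/(n₁n₂)`
exactly, a correspondence the test suite verifies on hundreds of random
instances. Two-variable performance is the separation fidelity of a fitted
line in the (whisker, eye) plane: the fraction of points on their own side,
1.0 for perfect separation, 0.5 when each side is perfectly mixed.

**Coupling.** Each saccade inside a backward epoch contributes one
lag-aligned whisker-asymmetry trace, signed toward the event's direction so
left- and rightward events pool. The null redraws each event's time
uniformly within its own trial's backward epoch, preserving directions and
per-trial counts. Real and null are compared per 100 ms bin of per-trace
medians with the Mann-Whitney U test, Bonferroni-corrected over bins, and
`estimate_lead()` reports the start of the earliest contiguous
significantly-elevated pre-saccadic bin.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| speed threshold | 0.1 | % eye width / frame | the empirically set detection threshold of the reference analysis |
| refractory window | 250 | ms | artifact-train rejection window of the reference analysis |
| conjugacy window | ±1 | eye frame (10 ms) | "approximately the same time" needs an operational window; one frame is the tightest nontrivial choice |
| prediction bins | 5 | — | the reference binning of the backward epoch |
| histogram bins | 10 | — | the reference per-epoch saccade histogram |
| correlogram bins | 100 | ms | the reference quantification bin |
| correlogram window | −0.5 … +0.8 | s | covers the plotted lag range; configurable |
| shuffles | 100–1000 | — | the reference count is unstated; seeded, configurable |

## The synthetic generator: what a green test establishes

`generator_config()` states a world; `generate_session()` realizes it with
full ground truth. Defaults: 20 trials, epochs of 1–4.5 s drawn uniformly,
200/100 Hz clocks, 10 Hz whisking sinusoid of 15° amplitude (within the up
to ~20 Hz whisking band; amplitude reduced to 20% in quiet states), peak
base asymmetry 30% of trial range rising through 90% of the backward epoch,
eye deviation 5% of eye width appearing in the last 40%, saccades at 0.5 /s
during backward movement (0.7× during turns, 0.5× forward) with amplitudes
~N(2.5, 0.8)% of eye width, 80% directed toward the cued turn, timing
density ∝ normalized time (latter-half weighting), a per-saccade asymmetry
increment of 15% with onset 150 ms before the event, and white measurement
noise (0.5° whisker, 0.02% eye). Values the underlying study does not print
(saccade amplitude statistics, noise scales, epoch durations) are free
parameters chosen once at scales a behavioral physiologist would call
realistic, not estimates.

Three generator design points deserve explanation:

* **Equal-dwell, symmetric-extreme asymmetry profile.** Per-trial range
  normalization is an extreme-value statistic: whatever the profile does at
  its extremes — including how *long* it dwells there and how measurement
  noise rides on top — enters every normalized sample of the trial. If the
  injected profile dwelt longer at its positive peak than at its reversed
  negative peak, the flat early-backward baseline would inherit a
  cue-direction-dependent offset and early-bin AUCs would be spuriously
  far from 0.5. The generator therefore holds the profile at +peak and at
  the turn reversal's −peak for the same fixed time (0.3 s), and the
  reversal depth adapts to the realized backward maximum (base ramp plus
  coupling increments), keeping the per-trial extremes symmetric by
  construction. The reversal itself mirrors the observed shape of real
  trials (asymmetry flips sign during the turn and unwinds during forward
  movement).
* **Coupling as pre-saccadic ramp onsets.** Each backward saccade adds a
  logistic-rise increment with onset `asymmetry_lead` seconds before the
  event (scale 10 ms), held for `coupling_hold` and decaying afterwards.
  This makes the correlogram's effect recoverable with a known lead while
  leaving the shuffled-timing null honest: when the lead is a bin
  midpoint, the lead bin is only half-risen, so detection legitimately
  needs pooled multi-session event counts (`pool_correlograms()`), as in
  the reference analysis, which pools hundreds of events.
* **Directions never consume randomness.** Cue directions only flip signs,
  so forcing a mirrored direction vector under the same seed yields exactly
  mirrored traces at zero noise — the mirror-symmetry property test.

What the generator does **not** emulate: blinks and occlusion artifacts
(an optional missing-data path exists, but no realistic artifact model),
pupil-diameter dynamics, whisk-cycle structure beyond a sinusoid (no
setpoint/amplitude decomposition, no slip-stick events), head or nose
movement, disconjugate eye movement, and any video-level realism. A green
suite therefore establishes that the *pipeline* recovers what it assumes
from data with the stated statistical structure — not that real videos
satisfy those assumptions.

## Numerical choices

* **Circle fit**: algebraic Kåsa least squares; closed form, exact on
  noiseless circles, adequate at whisker-arc curvatures. Collinear input is
  a fit error.
* **Ellipse fit**: direct conic least squares with the ellipse constraint,
  on centered/scaled coordinates for conditioning; non-elliptical best
  conics and degenerate configurations are fit errors. The "diameter" of an
  ellipse is ambiguous (major, minor, equivalent-area); all three are
  exposed and the equivalent-area diameter is the default summary.
* **Eye corners**: real roots of the quadratic difference of the two
  eyelid parabolas; complex roots (non-crossing lids) and coincident
  parabolas are geometry errors. The independent variable is the image
  horizontal axis, treating eyelids as functions of x.
* **Trial-range normalization** errors on constant (degenerate) trials
  rather than dividing by ~0.
* **Clock joining**: 200 Hz whisker traces are downsampled to the 100 Hz
  eye clock by 2-frame averaging — an exact factor, mildly anti-aliased.
* **The linear separator** is a deterministic closed form rather than an
  iterative perceptron: columns are standardized, the direction is the
  ridge-regularized Fisher discriminant, and the intercept maximizes
  accuracy by an exhaustive sweep over cut points (both orientations,
  ±∞ included). This realizes the stated fidelity contract — 1.0 on
  separable data, exactly 0.5 on label-duplicated data, never below the
  majority-class frequency (the ±∞ cuts are the majority rule) — with no
  iteration budget, no learning rate, and bit-reproducible results. The
  `seed` argument is accepted for interface stability but unused.
* **Shuffle-based tests use one designated surrogate set** as the null
  sample for Mann-Whitney comparisons: under no effect the real statistics
  and a single surrogate set are exchangeable, which gives the test its
  nominal level (verified by the type-I calibration criterion). The
  remaining surrogate sets only stabilize displayed null medians; pooling
  them into the test would understate the null's dependence structure.
* **Per-bin predictor units**: one value per epoch (the bin mean) for ROC —
  one decision per trial is the natural unit — and individual time points
  for the separator, matching the stated construction of each analysis; a
  `per` switch selects either.
* **Empirical vs across-session p-values**: `roc_analysis()` reports both
  a per-session empirical p (rank of the real AUC in its own null draws)
  and across-session Mann-Whitney comparisons; the across-session test is
  only meaningful with several sessions.

## Open design points, resolved

* The reference analysis leaves the ROC aggregation unit ambiguous
  (sessions vs pooled epochs; its own trial counts differ between figure
  legend and text). Here AUCs are computed per session and compared across
  sessions; pooling is available by passing a single concatenated table.
* Whether end-of-lane epochs are halved for the quiet-reference statistics
  is unstated; `epoch_summary(split_halves = TRUE)` implements the halving
  with a `floor(n/2)` boundary, flagged as a convention, not a recovered
  fact.
* Event-time shuffles preserve per-trial event counts (each event is
  redrawn within its own trial's backward epoch); pooling across trials
  would break the per-trial pairing the null is meant to preserve.
* Run configs are JSON (not YAML): equally diff-able, and supported by the
  guaranteed dependency set.
* The CLI exposes two subcommands (`run`, `simulate`) over a single staged
  pipeline with toggles, rather than one subcommand per stage; stage
  dependencies are validated and violations abort with the stage name.

## Known limitations

* The geometry stage consumes keypoints; it does not detect pupil edges or
  eyelid outlines from pixels (`hue_centroid()` is the only pixel-level
  operation, for whisker tracking).
* The refractory rule discards whole event trains, as stated by the
  reference method; with very high saccade rates this is conservative and
  the detector's recall claim applies to isolated (≥ 350 ms spaced) events.
* Fidelity values of shuffled models carry small-sample optimism (the
  intercept sweep can exploit noise); contribution tests therefore compare
  models against each other, never against the theoretical 0.5.
* Type-I calibration bounds in the acceptance suite are bands
  (0.005–0.10 at α = 0.05) because discrete rank tests are conservative at
  small per-session sample sizes.
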