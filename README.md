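# whiskeye

Analysis of coordinated whisker and eye movements in head-fixed mice
navigating a floating plus maze.

When a head-fixed mouse drives an air-lifted plus maze around itself, it
positions its two C2 whiskers asymmetrically before it turns, and moves both
eyes conjugately — in abrupt, saccade-like steps — toward the upcoming turn
direction. `whiskeye` re-implements the full quantitative pipeline for this
kind of experiment as a tested, reusable R package:

* **Geometry** — tracked pixels to physiological variables: luma-weighted
  hue-masked whisker centroids; a least-squares circle fit per whisker with
  polar-angle conversion; per-frame ellipse fits to eight pupil-edge
  keypoints; parabola fits to the eyelids whose intersections define the eye
  corners and the eye-width segment; pupil position as the projection onto
  that segment in fractions of eye width.
* **Kinematics** — session-median ("provisional zero") centering and
  per-trial range normalization of whisker angles to [0, 100]%; whisker
  asymmetry `w_R − w_L` signed toward the cued turn (`w_R − w_L` on
  left-turn trials, `w_L − w_R` on right-turn trials); head-centered
  conjugate pupil deviation; epoch time-warping onto a [0, 1] base.
* **Saccade detection** — pupil speed `dX/dt` in % eye width per frame; an
  event requires both eyes to cross a 0.1 %/frame threshold with the same
  sign; trains of crossings closer than 250 ms are discarded as artifacts;
  per-epoch 10-bin saccade histograms split by direction.
* **Turn prediction** — the backward-movement epoch split into 5 time bins;
  per-bin ROC curves and AUC (with the exact identity AUC = U/(n₁n₂) to the
  Mann-Whitney statistic); shuffled-label nulls; a deterministic linear
  separator in the (whisker asymmetry, eye position) plane whose *separation
  fidelity* is the fraction of points on their own side of the line, with
  shuffle-based unique contributions of each variable.
* **Saccade–whisker coupling** — saccade-triggered whisker-asymmetry
  correlograms during backward movement against a within-epoch
  shuffled-timing null, quantified in 100 ms bins of per-trace medians with
  Mann-Whitney tests and an automatic pre-saccadic lead estimate.
* **Statistics** — self-contained Mann-Whitney U (exact enumeration for
  small samples), Kruskal-Wallis, Dunn's post hoc, and Bonferroni
  correction.
* **Synthetic sessions** — a ground-truth generator that emulates the
  state-sequenced trials (end-of-lane → backward → turn → forward → expect →
  lick), mirror-image turn-dependent asymmetry, stepwise conjugate pupil
  deviation, late-backward saccade timing, and an asymmetry rise leading
  saccades by a configurable 100–200 ms, so every downstream stage is
  testable without any recorded data.

## Worked example

Six synthetic 20-trial sessions, analyzed end to end:

```r
library(whiskeye)
sessions <- lapply(1:6, function(i)
  generate_session(generator_config(n_trials = 20, seed = 42 + i)))
analyses <- lapply(sessions, function(s)
  analyze_session(s$session, list(seed = 42, n_shuffles = 100)))

roc <- roc_analysis(lapply(analyses, `[[`, "table_epoch"), n_shuffles = 200, seed = 1)
subset(roc$p_vs_null, predictor == "whisker")
#>   predictor bin median_auc median_null p_value
#> 1   whisker   1      0.969       0.500 0.00216
#> 2   whisker   2      1.000       0.500 0.00216
#> 3   whisker   3      1.000       0.500 0.00216
#> 4   whisker   4      1.000       0.505 0.00216
#> 5   whisker   5      1.000       0.497 0.00216
subset(roc$p_vs_null, predictor == "eye")
#>    predictor bin median_auc median_null p_value
#> 6        eye   1      0.547       0.500 0.33117
#> 7        eye   2      0.568       0.495 0.93723
#> 8        eye   3      0.656       0.500 0.69913
#> 9        eye   4      0.769       0.500 0.00866
#> 10       eye   5      0.923       0.500 0.00216
```

Whisker asymmetry predicts the cued turn from the very beginning of the
backward movement (median AUC 0.97 in bin 1, Mann-Whitney vs the shuffled
null p ≈ 0.002), while eye position becomes a reliable predictor only in
the later bins — the generator's stated world, in which the asymmetry ramp
starts early and the eye deviation appears late.

```r
cg <- pool_correlograms(lapply(analyses, `[[`, "correlogram"))
cg$n_events
#> [1] 171
estimate_lead(cg)
#> [1] -0.2
cg$bins[3:7, c("start", "end", "real_median", "null_median", "p_adjusted")]
#>    start    end real_median null_median p_adjusted
#> 3 -3e-01 -2e-01        13.4        6.50   8.75e-01
#> 4 -2e-01 -1e-01        20.0        6.73   1.85e-05
#> 5 -1e-01 -1e-09        29.7        7.10   1.75e-13
#> 6 -1e-09  1e-01        30.7        8.71   1.35e-13
#> 7  1e-01  2e-01        31.4        9.46   2.23e-14
```

Pooled across the six sessions (171 saccades inside backward epochs),
whisker asymmetry is significantly elevated above the shuffled-timing null
from the [−0.2, −0.1] s bin onward: the asymmetry rise precedes the
saccade by 100–200 ms, which is exactly the lead injected by the
generator (150 ms).

A whole run can also be driven from a JSON config:

```sh
Rscript -e 'whiskeye::main_cli()' run --config config.json --out results --seed 7
```

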