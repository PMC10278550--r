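---
title: "Measuring visual working memory encoding depth from gaze and pupil dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring visual working memory encoding depth from gaze and pupil dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In a copy task, a participant reproduces a pattern of six items shown on
the left half of the display by dragging items into a response grid on
the right. Looking back at the model is allowed but costly: an imposed
delay (200, 1500, or 3000 ms) must elapse, with gaze held on the left
half, before the model reappears. Each such left-screen visit that
survives its delay is a *sampling event*: the participant views the
model (*dwell time*), then crosses to the right and places items
(*build duration*). Because item-level placement records are not
available per event, build duration serves as the behavioural proxy for
how much was encoded into visual working memory (VWM) on that event —
longer building means more items were placed from memory.

Beyond these spatiotemporal gaze measures, two pupillary signals are
extracted per event:

* **Baseline pupil size** — the median pupil size over the 100 ms
  before model onset, an index of tonic arousal (alerting) at the
  moment encoding becomes possible.
* **Pupil orienting response** — the stimulus-locked constriction that
  begins roughly 200–300 ms after onset and resolves by roughly
  700–1200 ms; its amplitude indexes the depth of sensory processing.

The package's central question is whether these signals predict, trial
by trial and event by event, how much (build duration) and how
precisely (continuous-report error) material is encoded.

## Event segmentation

Gaze samples (1000 Hz) are classified left/right of the display
midline; a sample exactly on the midline counts as right (half-open
convention, so the classification is deterministic). Visits are
alternating left/right intervals with a **hysteresis rule**: an
excursion to the opposite half shorter than 100 ms does not end the
current visit — a visit ends only at the start of the first
opposite-half period sustained for at least 100 ms. Invalid samples
(blinks, track loss) inherit the current side, so a blink can never
split a visit. All intervals are half-open `[enter, leave)` in integer
milliseconds.

Per trial:

* a left visit at least as long as the trial's delay produces a
  sampling event with model onset at `visit start + delay`;
* shorter left visits are aborted samples — no event, and the delay
  timer does not carry over to the next visit;
* dwell time runs from the *dwell reference point* to the visit's end
  (the start of the first sustained right period), truncated at trial
  end;
* build duration runs from dwell end to the first sustained left
  return (`ended_by = "gaze-return"`) or the trial end
  (`ended_by = "trial-end"`); if gaze never reaches the right half
  before the trial ends, build is recorded as absent.

**Dwell reference point.** The verbal definition of dwell ("time until
gaze shifts back to the right side") leaves its start ambiguous. The
default here is model onset, because encoding-relevant viewing only
begins when the model is visible; `dwell_reference = "visit_start"`
switches to counting from the start of the left visit (which adds the
delay to every dwell). Both are exposed because either reading is
defensible; results in this package are reported under the
model-onset convention.

## Pupil features

Blinks are treated by padded linear interpolation: each invalid run is
extended by 50 ms on both sides (EyeLink pupil traces are distorted
just before and after a blink) and filled linearly from the flanking
valid samples; runs touching a recording edge stay invalid.
Interpolated samples are flagged `reconstructed`: they contribute
values to window medians but do not count toward window validity.

Window conventions are fixed so results are bit-reproducible at
1000 Hz:

| feature | window | statistic |
|---|---|---|
| baseline | `[-100, 0)` ms, half-open | median |
| orienting amplitude | `[500, 1000]` ms, closed | −(median of baseline-corrected trace) |
| control metric | max over `[0, 300]` minus min over `[500, 1000]` | extrema |

A window must contain at least 50% originally-valid samples for its
statistic to be computed; otherwise the metric is absent and the event
flagged (never silently guessed). The orienting amplitude is stored as
a **constriction magnitude** (positive = deeper constriction), so a
positive regression coefficient reads "stronger orienting, longer
build", matching the directional language of the field; the signed
median is available via `signed = TRUE`.

**Gaze-deviation filter.** Pupil-size estimates are biased by gaze
angle, so events are only analyzed if gaze stayed within 2 degrees of
the model grid for 1000 ms after model onset. The default
interpretation is *continuous* containment over `[0, 1000)` ms (the
stricter reading); a *cumulative* mode (total on-grid time after onset
of at least 1000 ms) is exposed because the verbal criterion does not
say whether interruptions are tolerated. The boundary of the expanded
grid rectangle is closed. This filter is also why the 200-ms delay
condition is excluded from analysis: its dwells are too short to give
reliable pupil estimates.

Robust z-scores (per participant: subtract the median, divide by the
unscaled median absolute deviation, no 1.4826 consistency factor) are
provided for visualization only; every model is fit on raw scales
(arbitrary recorder units; durations in seconds).

## The model stack

All models are linear mixed-effects models (`lme4`) with a
by-participant random intercept and random slope for delay condition,
which limits type-I errors for the condition contrast. Significance
uses `|t| > 1.96` (normal approximation, alpha = 0.05) with **no
degrees-of-freedom correction** — deliberately, to match the analysis
convention this pipeline implements. Condition is a two-level factor
(medium = 1500 ms reference), experiment a two-level factor
(experiment 1 reference).

* condition contrasts: `outcome ~ condition + experiment +
  (1 + condition | participant)` for dwell, build, baseline, and
  orienting;
* the central trial-level model: `build ~ baseline × experiment +
  orienting × experiment + dwell × experiment + condition +
  (1 + condition | participant)`;
* per-experiment follow-ups without the interactions;
* AIC selection (ML fits for fixed-effect comparisons, REML for
  reported coefficients; exact AIC ties go to the smaller model);
* continuous-report models: trials split into precise (≤ 15°),
  intermediate (> 15, ≤ 30°), imprecise (> 30°) groups — boundaries in
  the lower group; a time-resolved model per 10-ms bin,
  `pupil ~ group × set size × prototypicality +
  (1 + set size × prototypicality | participant)`, reporting
  uncorrected significant runs; and the trial-level model
  `error ~ baseline + orienting + set size × prototypicality +
  (1 + set size × prototypicality | participant)`.

**Degenerate-data policy.** Whole-table fits raise an error on a
constant outcome (a silent fit would be meaningless). The per-bin
time-course fits instead degrade gracefully, because degenerate bins
are routine there: a constant-outcome bin yields a non-significant
stub; if the mixed model cannot be fit (e.g. zero residual variance in
noiseless simulations), the fixed-effects linear model is used, with
`t = ±Inf` where the residual is exactly zero. Bins with fewer than
two precision groups are skipped and logged. Non-convergence of a
whole-table fit is flagged in the result, never silently repaired.

**Calibration note.** With 24 participants, the normal-approximation
rule is mildly anticonservative for predictors that carry substantial
between-participant variance: under a planted null, the baseline term
crosses `|t| > 1.96` in roughly 6% of replicates (what a
t-distribution with ~20 cluster degrees of freedom predicts), while
the condition term runs slightly conservative (~3%). This is the
price of the fixed-threshold convention and is left as is rather than
papered over with a df correction the convention does not use.

## The synthetic generators

Simulated data make every stage testable against known ground truth.
The copy-task generator's defaults emulate the study conditions this
pipeline targets: 24 participants split over two experiments, 35
trials per delay condition, medium/long delays, about 1.65 events per
trial (≈ 2,770 events in total), 11.4% of trials with placement
errors, baseline ≈ 3000 a.u. with a +1312.68 a.u. shift in experiment
2 (darker stimuli), orienting magnitudes ≈ 100 a.u. (+59.53 in the
long condition), lognormal dwells with median 1.2 s (+1.64 s in the
long condition), and planted build-duration effects
b(baseline) = 0.0009 s/a.u., b(orienting) = 0.003 and 0.0001 s/a.u.
and b(dwell) = 0.10 and 0.19 s/s in experiments 1 and 2. The direct
condition effect on build is 0 by default: the ≈ 0.33 s marginal
condition difference in build emerges entirely through the planted
dwell and orienting condition shifts, mirroring the mediation
structure in which condition ceases to predict build once the ocular
metrics are adjusted for. `marginal_condition_effect()` returns this
implied marginal estimand in closed form.

Design choices worth knowing:

* **Kernel.** Only the timing and amplitude of the orienting
  constriction matter for median-window features, so the kernel is a
  raised-cosine dip parameterized by onset (250 ms), trough (650 ms),
  and recovery (1000 ms). Planted amplitudes are divided by the
  kernel's median gain over the orienting window
  (`kernel_window_gain()`), so that in the noiseless limit the
  extracted feature equals the planted value exactly — parameter
  recovery then tests the pipeline, not the kernel's shape.
* **Gaze.** Fixations are jittered points well inside each half;
  saccades are instantaneous. Segmentation depends only on
  half-crossings and hysteresis, so saccade kinematics would add
  nothing to the tests. Sub-100-ms flickers to the opposite half are
  injected (strictly inside a run, so they cannot move a planted
  boundary) to exercise the hysteresis rule; aborted visits and
  gaze-deviation violations are available at configurable rates.
* **Build floor.** Planted build durations are floored at 0.1 s
  (durations are physical, and a sustained right period must outlast
  the hysteresis for the next visit to be detectable).
* **Baselines** are drawn per event around a per-participant mean,
  giving the within-participant variance the trial-level models need.
* **Experiment-relative arousal.** The build equation applies the
  baseline effect to the deviation from the experiment-specific
  baseline mean, since the between-experiment offset reflects stimulus
  luminance, not arousal.

The precision-task generator draws set size (1–4), prototypicality,
baseline, and orienting magnitude per trial and generates angular
error as a linear model (set-size slope 5.78°/item; baseline
+0.002°/a.u.; orienting −0.004°/a.u., i.e. stronger constriction,
smaller error) truncated to [0, 180]°, plus a stimulus-locked pupil
epoch per trial. A `group_effect_au` plant adds a pupil offset per
precision-group step inside a configurable window (half-open, so the
effect occupies exactly the bins whose left edges fall inside it);
it exists purely to validate the time-resolved models by
plant-and-recover.

**What the generators do not emulate:** realistic saccade kinematics
and microsaccades, pupil foreshortening with gaze angle, luminance
responses to the actual stimuli, slow tonic drift within a recording,
and any dependence of placement accuracy on pupil state. Passing
tests therefore demonstrate that the pipeline recovers what it is
defined to measure, not that those measurements are artifact-free in
real recordings — the gaze-deviation filter exists precisely because
the foreshortening artifact is handled by exclusion, not correction.

## Validation problem sizes

The test suite validates: exact segmentation against ground truth on
noiseless recordings (1 participant, 10 trials); the hysteresis rule
on 1000 random fixtures with excursions of 50–99 ms (never split) and
100+ ms (always split); feature extraction against sort-based
brute-force medians/extrema on 1000 random epochs (machine
precision); 95% CI coverage of all planted build-model effects over
100 replicates at full study scale with type-I calibration over 200
planted-null replicates; recovery of the 5.78°/item set-size slope at
24 × 100 precision trials; and exact recovery of a planted 500–1000 ms
time-course window (10 participants × 40 trials). `scripts/acceptance.R`
recomputes all of these from scratch under a caller-supplied seed.

## Limitations

Build duration is a proxy: it correlates strongly with the number of
correctly placed items (`validate_build_proxy()` implements that
check as a Spearman correlation), but when incorrect placements occur
it tracks those instead, so it is only a valid encoding-depth measure
on all-correct trials — which is why those are the only trials
analyzed. The ASC reader is a minimal subset (sample lines and blink
markers), not a general EyeLink parser; binocular data, calibration,
and fixation/saccade classification are out of scope. Time-course
significance runs are uncorrected for multiple comparisons, matching
the reporting convention they mirror.
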