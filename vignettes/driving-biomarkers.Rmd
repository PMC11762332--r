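---
title: "Turn-maneuver driving biomarkers: simulation, feature extraction and evaluation methodology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Turn-maneuver driving biomarkers: simulation, feature extraction and evaluation methodology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drivecog)
```

## The problem

Driving a car — and turning in particular — loads spatial orientation,
divided attention and processing speed, the cognitive domains that decline
early in mild cognitive impairment (MCI). drivecog implements a complete,
testable analysis pipeline for a standardized driving assessment: subjects
drive repeated laps of a fixed closed circuit under two instructed
conditions (normal and aggressive driving) while a vehicle-mounted sensor
array records a gyroscope and accelerometer at 10 Hz and GPS position/speed
at 1 Hz. Turn maneuvers are detected from the yaw-rate channel, summarized
into a 26-feature kinematic vector per subject, and used to classify
subjects as healthy or MCI under subject-level cross-validation. A
variance-weighted PCA-loading score then ranks which of the original
features drive the representation.

Because raw recordings from such assessments are typically private, the
package ships a session simulator that reproduces the protocol's geometry
and sampling design. Every downstream stage is exercised and tested against
simulated cohorts whose ground truth is known exactly.

## The simulator

### Circuit

`build_circuit()` composes a closed lap of straight sections, 90° left and
right turns, and 180° U-turns. The default lap is 540 m: two U-turns
(radius 8 m, both leftward so signed heading changes close at $+2\pi$), two
left and two right 90° turns (radius 10 m), and six straights padded to the
lap length. The turn counts per lap are a documented choice — the protocol
prescribes "a combination" of turn types without counts — and are fully
configurable; any composition whose signed heading changes sum to $\pm2\pi$
is accepted.

### Kinematics

`simulate_session()` builds each turn's yaw-rate trace as a trapezoidal
lobe: ramp at the style's yaw-ramp rate $\rho$ up to the peak yaw rate,
plateau, ramp down (degenerating to a triangle for small angles). Two
discrete calibrations make the generated data exact rather than
approximately right:

* the sampled lobe is rescaled so its discrete time integral equals the
  segment's designed heading change exactly — cumulative heading therefore
  advances by exactly $2\pi$ per lap at zero noise, and lap counting is a
  matter of arithmetic, not tolerance;
* straights carry a trapezoidal speed profile (brake at the style's
  longitudinal acceleration to the next turn's speed, cruise, accelerate
  out), rescaled so each lap's travelled distance equals the lap length
  exactly. Braking *ends at the turn entry*, so the 1 Hz GPS speed stream is
  constant through each turn window and linear interpolation does not smear
  straight-line speed into turn features.

Default style parameters: normal driving turns at 4 m/s with peak yaw rates
0.4 rad/s (90°) and 0.6 rad/s (U-turn), cruises at 8 m/s, ramps yaw at
0.2 rad/s²; aggressive driving turns at 7 m/s with yaw peaks scaled 1.6×,
cruises at 11 m/s, ramps at 0.5 rad/s². These clear the default detection
threshold (0.15 rad/s) by ≥2.7×. Sensor noise is additive Gaussian per
channel (0.02 rad/s gyro, 0.05 m/s² accelerometer, 0.2 m/s GPS speed); GPS
positions are dead-reckoned from the planar trajectory and expressed as
WGS-84 degrees around a configurable origin.

### Cohort structure and the status effect

`generate_cohort()` layers three sources of variation:

* **between subjects** — each subject draws speed and yaw multipliers from
  $\mathcal N(1, 0.10)$, so subjects have stable personal driving styles;
* **within subjects** — each turn of each lap jitters its speed and peak yaw
  rate with a 5% CV;
* **status effect** — at `effect_size` $s$, MCI subjects' turn speed and
  peak yaw rate are multiplied by $1 - 0.15s$ and their within-subject
  jitter CV by $1 + 0.30s$. At $s = 0$ the status-conditional distributions
  are identical by construction; the defaults encode the premise that
  impairment slows and destabilizes turning, with magnitudes that are
  simulator parameters, not empirical claims.

The default roster is the packaged 21-subject reference cohort (13 healthy,
8 MCI, ages 65–85). All child seeds derive from one master seed by stable
string hashing, so cohorts are byte-reproducible.

What the simulator does **not** emulate: vehicle dynamics (tire slip,
braking transients), road curvature tracking errors, GPS multipath or
position drift, traffic, or any within-session fatigue/learning trend.
Passing tests on simulated cohorts therefore demonstrate the correctness of
the pipeline's mechanics and its statistical hygiene, not field performance
on real drives.

## Turn detection and the 26 features

`detect_turn_events()` synchronizes GPS speed onto the gyro timeline by
linear interpolation (clamping to edge values outside the GPS span),
smooths the yaw rate with a 0.5 s centered moving average, and finds
turning maneuvers as contiguous excursions of $|\omega|$ above 0.15 rad/s.
Excursions of equal sign separated by less than 2 s are merged — threshold
flutter on a long turn ramp must not fragment the maneuver — and each
maneuver's window extends outward from the peak until $|\omega|$ falls
below 10% of the peak amplitude, clipped at the midpoint to the adjacent
peak. The smoothing window exists because the maximum of a noisy plateau is
biased upward by the noise extremes; 0.5 s restores mean-peak recovery to
within a few percent at the default noise level without displacing peak
locations.

Each window is classified by its trapezoidally integrated angle: $\geq$135°
is a U-turn, 45°–135° a 90° turn (left = positive yaw, configurable for
inverted mountings), below 45° a *minor* turn. Minor turns, and any event
nested inside a U-turn window, are excluded. Angular acceleration is the
discrete derivative of consecutive yaw-rate samples,
$\alpha = \Delta\omega / \Delta t$ with $\Delta t$ the 0.1 s sampling
interval — the consecutive-sample reading is the only one that yields
distinct per-turn maxima and minima. On the simulator's trapezoidal lobes
the extrema recover $\pm\rho$ exactly at zero noise.

`extract_features()` fills the fixed 26-slot schema with means over all
events matching each (condition, turn type): mean |peak yaw rate| (6),
mean of per-turn maximum and minimum angular acceleration (12), mean turn
speed (6), and mean U-turn duration (2). Velocity magnitudes are reported
unsigned so left and right turns are comparable. Combinations with no
events are `NA` with a missing-mask flag; imputation happens later, inside
the cross-validation fold, never globally.

## Evaluation without leakage

Subject-level data violate the i.i.d. assumption behind record-level
cross-validation: a model can recognize a *driver* rather than a *status*.
`cross_validate()` therefore partitions **subjects** into stratified folds
(`assign_folds()`; per-status test counts differ by at most one). All
preprocessing — missing-feature imputation by training means, z-scoring,
and PCA — is fitted inside each fold on training subjects only; the
default 5 retained components explain roughly 85% of training variance on
the default cohort. Six classifiers with fixed, conventional
hyperparameters are compared: SVM (C = 1, RBF, $\gamma = 1/(d\,\mathrm{Var}(X))$),
random forest (100 trees), AdaBoost (50 depth-1 stumps, learning rate 1),
5-nearest neighbors, QDA, and L2 logistic regression (C = 1). No
hyperparameter tuning is performed anywhere. The AdaBoost learner is
implemented in-package (discrete AdaBoost over `rpart` stumps); the other
five call the standard R implementations.

MCI is the positive class. Per fold we record the confusion counts and
accuracy, sensitivity, specificity, PPV and NPV; a metric with a zero
denominator is *undefined* and excluded from the across-fold mean (the
number of contributing folds is reported alongside), never coerced to
zero. With 2 MCI test subjects per fold, undefined PPVs are a routine
occurrence, which is why the convention matters. Means and standard
deviations are computed at full precision and only formatted as
percentages for display.

An automated leakage guard is part of the test suite: no subject ID may
appear in both train and test of any fold, and the stored per-fold
preprocessors must equal what the training rows alone produce (and differ
from what train+test rows would produce).

## Feature contribution

For each fold's PCA with loadings $w_{ij}$ (component $i$, feature $j$;
rows unit-norm) and explained-variance ratios $\gamma_i$,

$$\mathrm{contribution}_j \;=\; \sum_{i=1}^{5} |w_{ij}|\,\gamma_i ,$$

summed across folds and ranked (ties broken by schema index). Variance
*ratios* rather than raw eigenvalues are used as $\gamma$, matching the
cumulative-variance convention used to choose the component count. Scores
are reported unnormalized; a normalized variant (share of total) is
available as a clearly labeled extension. Two bounds follow from unit-norm
loading rows and are asserted on every fitted model: each score is at most
$\sum_i \gamma_i$, and the scores sum to at most $\sqrt{26}\sum_i\gamma_i$
(Cauchy–Schwarz).

## Numerical choices and degenerate inputs

* Integrals of sampled signals use the trapezoidal rule; the simulator's
  per-segment calibration makes lap-level heading and distance exact at
  zero noise (tolerances in tests cover the noisy case).
* Zero-variance features in a training fold have their scale clamped to 1
  with a warning rather than producing NaNs.
* Single-class training data yield a constant predictor with a warning —
  folds remain comparable instead of aborting the run.
* Sign ties in peak plateaus resolve to the plateau midpoint; contribution
  ties break by feature index; fold assignment is deterministic given the
  seed.
* The serialization format prints 9 significant digits, enough for
  bit-stable round trips at sensor noise scales; timestamps are seconds
  from session start.

## Problem sizes

The default study conditions — 21 subjects × 2 conditions × 10 laps of
540 m, six models, k = 4 — run end to end in well under two minutes on one
CPU. The test suite additionally uses two 40-subject cohorts (high
separation, `effect_size = 3`, and null, `effect_size = 0`) to check that
classification succeeds when the effect is large and stays at chance when
there is none; a binomial 95% band around the majority share is the
pass criterion for the null cohort.

## Known limitations

* The 26-feature schema's "average angular velocity" is read as the mean of
  per-turn *peaks* (the detection stage isolates per-turn peaks); a
  mean-over-in-turn-samples reading is defensible and would be a small
  extension.
* U-turn duration is the detected window length (end minus start time),
  which systematically under-measures the designed lobe by the sub-boundary
  tails; it is consistent across subjects and conditions, which is what the
  comparison needs.
* The packaged reference fold map (`reference_fold_table()`) preserves the
  published table's internal anomalies verbatim (an ID beyond the roster,
  one roster ID absent, status assignments that disagree with the roster);
  it is a regression fixture, not an analysis input.
* With 8 MCI subjects in the default roster, per-fold metrics are coarse
  (multiples of 1/2 for sensitivity); across-fold standard deviations are
  correspondingly large. This mirrors the scale of the assessment the
  pipeline models and is why the structural properties, not the headline
  accuracies, are the tested quantities.

## A worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(seed = 17)
res <- run_pipeline(cfg, "run17")
print(res$cv)
head(as.data.frame(res$contributions))
make_report("run17")
```
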