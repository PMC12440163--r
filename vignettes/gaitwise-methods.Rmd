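---
title: "Classifying gait impairments from multi-view pose time series: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying gait impairments from multi-view pose time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Observational gait assessment is subjective; marker-based motion capture is
accurate but expensive. A middle path is markerless analysis: a phone camera
films a short overground walk, an on-device pose estimator extracts a
33-landmark skeleton per frame, and only the pose time series — not the
video — is analysed. `gaitwise` implements the full downstream pipeline for
classifying seven gait patterns from such series: normal gait (NOR) and six
clinically defined impairments — circumduction (CIR), Trendelenburg (TRE),
antalgic (ANT), crouch (CRO), Parkinsonian (PAR) and vaulting (VAU) — as
observed from a frontal and a sagittal camera view.

Because clinical pose recordings cannot be redistributed, the package also
ships a synthetic generator that produces labelled multi-view pose datasets
with the kinematic structure the analysis assumes. Every stage of the
pipeline is therefore exercisable, end to end, without any external data.

## The synthetic gait generator

The generator is a procedural kinematic walker, not a musculoskeletal
model. A subject is an anthropometric scaling (stature drawn from
N(1.70 m, 0.07 m), segment lengths as standard fractions of stature). The
gait cycle is parameterised by phase: each leg follows a stance/swing
pattern with duty factor 0.62, the ankle traces a single-hump vertical
clearance profile beginning at heel-off, and the knee is placed by exact
two-link inverse kinematics (so bone lengths are constant by construction).
Pelvis, trunk, arms (counter-swinging pendulums) and a rigid head complete
the skeleton. At zero impairment the walker is exactly left/right symmetric
under a half-cycle phase shift.

Each impairment class is a set of kinematic modifiers that scale linearly
with an `impairment_magnitude` in [0, 1] (all modifiers vanish at 0, so
every class degenerates to normal gait):

* **CIR** — a lateral semicircular arc of the affected swing leg
  (0.14 m at magnitude 1);
* **TRE** — contralateral pelvic drop during affected-side stance (0.05 m),
  with a slight compensatory trunk lean;
* **ANT** — the affected side's stance fraction and step length shortened
  by up to 30%;
* **CRO** — hip height lowered by up to 14% through sustained knee/hip
  flexion, plus a mild trunk pitch;
* **PAR** — arm swing reduced by up to 80%, trunk pitched forward up to
  0.3 rad, with short strides and raised cadence;
* **VAU** — pelvis lifted on the unaffected stance leg during affected
  swing (0.06 m).

Asymmetric classes affect the right side by default, mirroring common
standardisation in simulated-impairment protocols; a left-side switch is
provided.

**Walking-speed calibration.** Per-class stride-length and cadence ranges
are part of the configuration. Stride means are calibrated so that the
number of gait cycles visible in a rendered video matches clinically
typical per-class counts for 10 m walks (ANT 7.6, CIR 5.8, CRO 7.2, NOR
4.6, PAR 10.4, TRE 6.4, VAU 5.4 cycles per video). Two facts interact here:
the walk path is 10 m, but a fixed camera's field of view covers only part
of it, and frames without a visible subject are excluded. We pin the
visible path length at 6.4 m, which makes the calibrated strides
physiologically sensible (NOR ≈ 1.39 m, PAR ≈ 0.62 m) while reproducing the
cycle counts. Cycle counts are verified by `count_gait_cycles()`, a
peak-counting routine on the detrended affected-side heel height (used only
for calibration, never for classification). Peak counting loses about half
a cycle at the video edges; the resulting means still bracket the clinical
values and preserve their ordering.

**Rendering.** The sagittal camera (4 m from the walking line) is modelled
with constant scale — at that distance, panning keeps the subject's
perspective size nearly constant. The frontal camera sits on the path axis
2 m before its start, so the projection is a true pinhole: pixel size is
proportional to 1/distance, and the walker shrinks or grows along the walk
(walking "right" moves away from the camera; "left" approaches it). The
depth channel is the hip-relative distance of each landmark from the
camera, expressed in pixel-like units, and carries more noise
(default SD 6) than the planar jitter (default SD 2 px) — monocular depth
is the least reliable channel of on-device pose estimators. Occlusions are
independent Bernoulli events per landmark-frame (default probability 0.02)
recorded as missing values; real occlusion is temporally correlated, which
this deliberately simple model does not reproduce.

The noise stream of a video depends on the subject, view and direction but
not on the class label, so that identical trajectories (e.g. every class at
magnitude 0) render to identical sequences — the degenerate limit used by
the null-control experiments.

**What the generator does not emulate.** Pose-estimator failure modes other
than jitter/occlusion (identity swaps, systematic bias), soft-tissue and
clothing artefacts, inter-stride variability within a walk, fatigue, and
compensatory movements beyond the pinned modifiers. Passing tests on this
generator demonstrate that the pipeline recovers class structure of the
kind the protocol assumes; they are not evidence about any particular
clinical dataset.

## Preprocessing

The pipeline order is fixed: drop empty frames → interpolate missing
landmarks (linear in time; leading/trailing gaps take the nearest observed
value, where pure interpolation is undefined) → resample to 30 fps (linear
interpolation onto a uniform grid, robust to non-integer ratios; recordings
below 30 fps are rejected rather than upsampled) → hip-centre → height-
rescale (frontal only) → segment into windows.

Hip-centring subtracts, per frame and channel, the median hip midpoint over
a 2 s (61-frame) window centred on the frame; the median window is clipped
at sequence boundaries rather than padded. Median centring removes camera-
position bias and slow drift while preserving natural hip sway within the
window. Frontal sequences are additionally divided by a smoothed body-height
estimate — the nose-to-ankle-midpoint vertical extent, median-smoothed over
the same 2 s window — and multiplied by a fixed reference height (400 px),
removing perspective size change. Sagittal sequences skip rescaling. The
depth channel is centred and rescaled like x and y. No preprocessing step
reads the gait label.

Preprocessed sequences are cut into 30-frame (1 s) windows with 50%
overlap; trailing partial windows are discarded. Windows are fixed-stride,
not aligned to gait events. One window is a 30 × 99 matrix (33 landmarks ×
3 channels).

## The feature bank

Every catalogue entry (a feature type plus a parameter set) is evaluated on
every keypoint-channel series of every window. Two pinned catalogues exist:
the **full** catalogue has exactly 783 entries per channel — 99 × 783 =
77,517 candidate features per window set — mirroring the size of the
comprehensive catalogue of the established Python feature-extraction
ecosystem; the **reduced** catalogue (71 entries per channel, 7,029
features) is the default for analyses and tests and was fixed, before any
experiments were run, to keep end-to-end evaluations fast. The exact
parameter grids are pinned in `feature_catalog()`.

Numerical conventions, chosen once and mirrored exactly by the independent
NumPy/SciPy oracle used in the tests:

* variance and standard deviation are population moments (divide by n);
* `variation_coefficient` is sd/mean (0 when the mean is 0); the
  conventional definition is pinned deliberately even though some published
  tabulations gloss it as "standard error / mean";
* sample entropy uses m = 2, tolerance 0.2 sd, Chebyshev distance,
  −ln(A/B); approximate entropy uses tolerance r·sd and includes
  self-matches; permutation entropy is the Shannon entropy (natural log) of
  stable-argsort ordinal patterns;
* `fourier_entropy` is the binned entropy of the max-normalised
  single-segment Welch spectrum (Hann window, constant detrend; the segment
  length is min(n, 30), i.e. one segment for 30-sample windows);
* `fft_coefficient` angles are reported in degrees; `fft_aggregated`
  moments treat the magnitude spectrum as a distribution over
  frequency-bin index;
* `cwt_coefficients` convolve with the closed-form Ricker wavelet,
  support length min(10·width, n), "same"-mode alignment;
* `max_langevin_fixed_point` quantile-bins (x_t, Δx_t) into r = 30 bins,
  fits a cubic to the bin means and returns its largest real root;
* any non-finite feature value (0/0, log 0, undefined correlations on
  constant series) becomes 0, with a message, so the matrix is always
  finite;
* Mann–Whitney relevance p-values (below) are exact for small tie-free
  samples and use the tie- and continuity-corrected normal approximation
  otherwise.

The evaluation loop is in C++ (windows × 99 channels × catalogue is the hot
path); the exported per-family helpers (`moment_statistics()`,
`entropies()`, `spectral()`, ...) call the same engine, so there is a single
code path to validate.

## Selection and balancing

Feature relevance is tested univariately: for each feature and each class,
a two-sided Mann–Whitney U test of that class's windows against all others.
The Benjamini–Yekutieli step-up procedure — valid under arbitrary
dependence, with the harmonic-number correction c(m) — is applied jointly
across the full feature × class p-matrix at FDR level q = 0.05, and a
feature is kept if it is significant for at least one class. Survivor
counts are also reported per feature type, the unit in which selection
results are usually summarised. An empty selection falls back to the full
matrix with a warning. The multiclass handling (one-vs-rest per class,
keep-if-any) and q = 0.05 are pinned design choices.

Class imbalance (slower gaits yield more windows per video) is corrected by
SMOTE: each minority class is upsampled to the majority count by
interpolating between a sample and one of its k = 5 same-class nearest
neighbours with U(0, 1) weights; k shrinks to n−1 in tiny classes and
singletons are duplicated. Selection runs first, SMOTE second (interpolating
in the reduced space). Synthetic rows inherit the subject of their base row
so that subject-grouped inner cross-validation remains user-independent.

Both steps are fitted inside each training fold only; the evaluation driver
asserts structurally that no held-out subject's rows reach them.

## Evaluation

`nested_loso_evaluate()` runs user-independent nested cross-validation:
the outer loop leaves one subject out; within each fold, selection and
SMOTE are fitted on the training subjects, hyperparameters are tuned by
seeded random search scored with a subject-grouped 5-fold inner split
(3-fold with a warning below five training subjects), and the tuned model
is refitted and applied to the held-out subject. Three classifier families
are available — kernel SVM, random forest, and gradient-boosted trees —
with conventional tuning surfaces; the numeric ranges are pinned in
`model_spec()`. The boosted-tree space deliberately uses strong per-tree
column subsampling (0.1–0.5) and shallow trees: the feature matrices here
are wide, and decorrelated shallow trees are both faster and at least as
accurate on them.

Window predictions are aggregated by majority vote to video labels, and by
pooling both views' window labels to fused subject × class × direction
labels (a view contributing more windows carries proportionally more
weight; a missing view degrades to the single-view vote). Vote ties break
by highest mean class score, then lexicographic class code. Both walking
directions are pooled as training windows; fused votes are computed per
direction. Metrics (accuracy, precision, recall, F1) use weighted
averaging — test sets are class-balanced by design, so weighted and macro
averaging nearly coincide. Repeated trials rerun the scheme under seeds
that change inner-fold assignment, sampler draws and SMOTE draws (outer
LOSO folds are fixed by design), and summaries are mean ± 1.96 SE across
trial × fold scores.

Single-view performance is read off the same combined run by restricting
video-level predictions to one view (`video_accuracy_by_view()`), which is
what fused voting is compared against.

## Interpretation

Permutation importance: permute one feature column on held-out data,
rescore, repeat; importance is baseline accuracy minus mean permuted
accuracy, with a normal-approximation 95% CI over repeats. Positive values
mean the model used the feature; the scorer is pinned to accuracy on the
held-out outer fold (leakage-safe). `cv_permutation_importance()` averages
per-feature importances across outer folds, taking features outside a
fold's selected set as exactly 0. Importances are aggregated by summing
over each keypoint channel (`keypoint_importance()`), and the top-20
channel × feature-type cross table (`top_k_heatmap_table()`) is the usual
heatmap structure.

Permutation importance on heavily redundant feature sets concentrates near
zero — the model can compensate for any single permuted feature — and
per-class walking-speed draws act as a within-subject confound that models
overfit, producing noisy, even negative, channel importances. The packaged
lower-limb-dominance experiment therefore (i) restricts to circumduction
and antalgic signatures, which modify only leg kinematics, (ii) pins
stride length and cadence to exactly the normal values for those classes,
so speed carries no information, (iii) uses a mild severity (0.25) and a
lean 32-entry catalogue subset, concentrating the class signal in few
channels, and (iv) averages importances over all outer folds with eight
permutation repeats. Under this design the summed lower-limb channel
importance is reliably positive and the upper-limb sum is essentially
zero.

## Problem sizes used by the packaged experiments

The test-suite and acceptance-script experiments use, as the package's own
choice of desk-scale problem sizes: 10 subjects × 7 classes × 2 views × 2
directions (280 videos, ≈ 3,600 windows) for the headline class-recovery
run, with the reduced catalogue, boosted trees, a tuning budget of one
seeded draw from the pinned space, and 2 trials of nested LOSO; 6 subjects
for the null-control (within-subject label permutation) and importance
experiments; and 3 severity levels (0, 0.5, 1) at 6 subjects, sagittal
view, for the monotonicity check. The tuning machinery itself is validated
separately on small synthetic feature sets with larger budgets.

## Known limitations

* The walker is stylised: joint angles are not validated against
  biomechanical norms, there is no double-float or push-off dynamics, and
  pelvis bob is prescribed rather than emergent.
* Occlusions are independent across landmarks and frames.
* Hip-centring and height smoothing use clipped medians at sequence
  boundaries, so boundary frames are less stable than interior frames
  (preprocessing is idempotent to within re-estimation tolerance away from
  the edges).
* On near-separable synthetic data, permutation importances of individual
  redundant features are mostly zero; keypoint-level sums remain
  informative.
* The BY step-up controls FDR under dependence but the one-vs-rest U tests
  are univariate; multivariate relevance is out of scope.
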