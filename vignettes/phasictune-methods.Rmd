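---
title: "Quantifying direction tuning of phasic muscle activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying direction tuning of phasic muscle activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

When a person points rapidly in different directions, the nervous system
does not retune every muscle uniformly: muscles whose action opposes the
gravity torque at the shoulder (antigravity muscles such as the anterior
and medial deltoid, trapezius and biceps brachii) behave differently from
muscles whose action gravity assists (posterior deltoid, latissimus dorsi,
long triceps). Surface EMG can be split into a *tonic* component — the
baseline activity that holds the limb against gravity — and a *phasic*
component, the movement-related remainder. The phasic trace of an
antigravity muscle routinely dips **below zero**: the muscle produces less
activity than gravity compensation alone would require. These negative
phases appear exactly where gravity helps the motion — the acceleration
half of downward movements and the deceleration half of upward movements —
and are a signature of effort-optimal control rather than an artifact of
the decomposition.

`phasictune` packages a complete, testable pipeline for asking *how finely
this deactivation (and collective muscle activity in general) is tuned to
pointing direction*. Because the human recordings this methodology was
developed on are not publicly released, the package ships a synthetic-EMG
generator that emulates their statistical structure, so every stage — and
every claim made by the analyses — can be exercised end to end on data
with known ground truth.

## From raw EMG to classifier inputs

The preprocessing chain mirrors standard motor-control practice:

1. **Rectify and band-pass** (`rectify_and_filter()`): full-wave
   rectification and a third-order zero-phase Butterworth band-pass,
   20–300 Hz. Rectify-then-filter is the default order; the alternative
   order is a flag. Zero-phase (forward–backward) filtering preserves
   burst timing; the cost is start-up transients within roughly a filter
   length of each edge, which fall inside the quiet margins and never
   touch the movement window.
2. **Envelope** (`rms_integrate()`): trapezoidal integration over a
   centered 5 ms sliding window, normalized by window length so constant
   signals are fixed points. Windows shrink at the edges rather than
   padding with fabricated samples. `mode = "rms"` integrates the squared
   signal and takes the root; this proper RMS variant is the one that
   demodulates an amplitude-modulated interference signal, and is what the
   end-to-end recovery demonstrations use.
3. **Tonic estimate** (`estimate_tonic()`): the envelope is averaged from
   1 to 0.5 s before movement onset and 0.5 to 1 s after movement stop;
   the straight line between those two values, anchored at the onset and
   offset samples, is the tonic activity across the movement.
4. **Phasic extraction** (`extract_phasic()`): envelope minus tonic over
   the movement interval. Negative values are *never* clipped — they are
   the object of study.
5. **Duration normalization** (`time_normalize()`): linear interpolation
   onto 1000 points, so trials of different durations are comparable
   point by point.
6. **Z-scoring** (`zscore_normalize()`): within each
   (subject, muscle, angle) cell, all time points of all trials are pooled
   and transformed to zero mean, unit variance. Per-subject normalization
   removes inter-individual amplitude differences; per-muscle keeps
   small muscles in play; per-angle deliberately removes amplitude
   information about direction, so any classifiable signal must live in
   waveform *shape*. Zero-variance cells map to zeros with a warning
   rather than an error, keeping degenerate synthetic inputs usable.

A trial's classifier input is the concatenation of its nine muscle
waveforms — a 9000-point vector (`concat_muscles()`). Sub-analyses slice
this vector by muscle group (`select_muscles()`), by movement half
(`select_phase()`; acceleration = first 500 normalized points, since rapid
point-to-point movements have near-midpoint velocity peaks and no
kinematic trace accompanies the EMG), or by negativity: `negative_part()`
zeroes positive samples and keeps negative ones, `binarize_negativity()`
maps strictly negative samples to 1 and everything else to 0, leaving
*only the timing* of deactivation. Both transforms preserve vector length
so rows stay commensurable, and both operate on the Z-scored waveforms —
the inputs the classifiers actually see — so "negative" means below the
cell's pooled mean in Z units. Exact zeros are classed with the positives.

## Classifiers as separability meters

The analysis never tries to maximize accuracy; classification accuracy is
used as an index of how separable two direction conditions are. Every task
is binary: the 90° horizontal plane (gravity-neutral, the reference)
against one comparison direction.

**Linear discriminant analysis** (`fit_lda()`, `predict_lda()`). Both
classes are modeled as Gaussians with a shared covariance. The predicted
class minimizes the expected misclassification cost; with 0–1 cost this is
the maximum-posterior class, with posteriors from Bayes' theorem, the
class-conditional likelihood determined entirely by the Mahalanobis
distance, and the normalizer pooled over the class likelihoods. Exact
posterior ties go to the lower class index, for determinism.

With p = 9000 features and under ~100 training rows, the pooled covariance
S is badly singular. The package shrinks it toward its diagonal,
(1−λ)S + λ·diag(S), with λ = 0.5 by default (configurable). The shrunk
matrix is never formed: solves go through the Woodbury identity on the
n-dimensional factor of S, so a fit costs O(n²p) rather than O(p³). With
λ = 0 and p > n an SVD pseudo-inverse is the documented fallback. Features
with zero pooled variance (common after binarization) are dropped at fit
time and recorded in the model.

Alongside accuracy, every fitted two-class model yields the **distance
between its class means** (`lda_distance()`), in Z-scored feature units.
Unlike accuracy, this index does not saturate: once two directions are
perfectly classifiable, accuracy pins at 1 while the mean distance keeps
growing, so the distance is the better probe of tuning at large angular
separations.

**Linear SVM** (`fit_linear_svm()`). The soft-margin problem —
minimize 0.5‖β‖² + CΣζ subject to the margin constraints — is solved in
the Lagrangian dual by sequential minimal optimization with second-order
working-set selection: the first index maximizes the KKT violation, the
second maximizes the guaranteed objective decrease. Iteration stops when
the maximal violation falls below 1e-5 (an iteration cap raises a labeled
error with diagnostics). The hyperplane normal is recovered as
β = Σαⱼyⱼxⱼ, the bias from the free support vectors (or the violation
midpoint when none are free), and the geometric **margin width** is
2/‖β‖ — the SVM's analogue of the class-mean distance. The box constraint
defaults to C = 1.

**Cross-validation** (`stratified_kfold()`, `cross_validate()`).
Stratified five-fold CV keeps both directions equally represented in every
split; folds are disjoint, covering, within one sample of the global class
proportions, and deterministic under a seed. Accuracy is the unweighted
fraction correct (the designs are balanced); the separability index is
averaged over the five per-fold models, the only aggregation unit
available per task.

## Nonparametric statistics

Fold-level and angle-level comparisons use exact small-sample tests:

- `wilcoxon_rank_sum()` reports the Mann–Whitney U of the first sample as
  W (its minimum, 0, occurs at complete separation) and, whenever the
  combined sample size is at most 12, an exact two-sided p-value by full
  enumeration of all C(n₁+n₂, n₁) group assignments of the pooled
  midranks. Two fully separated groups of five — e.g. five cross-validation
  fold distances per condition — give p = 2/252 ≈ 0.008 analytically.
  Beyond n = 12 a tie-corrected normal approximation with continuity
  correction takes over. The rank-biserial correlation
  (`rank_biserial()`) is the paired effect size: the signed proportion of
  cross-group pairs, ±1 at complete separation.
- `friedman_test()` ranks conditions within blocks (midranks on ties) and
  uses the tie-corrected χ² statistic on k−1 degrees of freedom;
  `kendalls_w()` = χ²/(n(k−1)) is its concordance effect size in [0, 1].
  The group comparison blocks on (comparison angle × CV fold) cells — the
  finest exchangeable unit the pipeline produces.
- `fit_slope()` is ordinary least squares of accuracy against angular
  distance from 90°, in degrees, fitted separately for upward (< 90°) and
  downward (> 90°) directions; R² is defined as 0 for constant responses.

## The synthetic generator

`generator_config()` defines a full factorial campaign; the defaults are
the study conditions: 11 subjects, 10 trials, 9 muscles
(4 antigravity, 3 gravity, 2 neutral), 17 directions at 15° spacing with
90° as reference. Since 17 directions at 15° cannot span 0°–180° exactly,
the default list spans 0°–240° and the span is configurable; the
scaled-down analyses in the test-suite use a 9-angle subset of 0°–180°.

Each muscle's phasic waveform is a sum of three Gaussian bursts
(agonist–antagonist–agonist, the classical triphasic pattern), with
per-trial jitter of burst centers (SD 0.05 of movement time), log-normal
per-trial amplitude jitter (SD 0.25), log-normal per-(subject, muscle)
scales (SD 0.3, removed by Z-scoring) and white noise (SD 1.0). Direction
tuning is linear in the angular distance Δ = |angle − 90|:

- **Antigravity deactivation**: a compactly supported cosine-squared lobe
  of depth `negativity_base_depth + negativity_depth_gain·Δ` and duration
  `negativity_duration_gain·Δ` (fraction of movement time, capped at 0.45
  so the lobe stays inside its half), centered at 0.25 of the movement for
  downward and 0.75 for upward pointing — where gravity assists the
  motion. The base-depth term lets *duration-only* tuning exist: with the
  depth gain at zero, lobes keep a constant depth while their duration
  still scales with Δ, the configuration under which only
  `binarize_negativity()` features should carry information.
- **Burst reshaping**: the first burst is scaled by (1 + g·Δ) and the last
  by its reciprocal — a shape change, because a uniform gain would be
  erased by the per-angle Z-score — with g = 0.003/° for antigravity and
  0.0015/° for gravity muscles; neutral channels are untuned.
- **Up/down asymmetry**: all downward effects are multiplied by 1.3,
  making the 180° condition more separable from 90° than the 0° condition,
  the asymmetry the up/down Wilcoxon comparison is designed to detect.

The default gains were calibrated once so that the scaled-down all-muscle
tuning curve reproduces the qualitative accuracy range reported on human
data — near chance at 15°, approximately linear growth, saturation toward
1 by 60–90° — rather than saturating everywhere, which stronger settings
do.

Raw trials (`generate_raw_trial()`) embed the waveform in a sampled
recording: the activity envelope is the tonic level plus the mapped phasic
waveform (floored at zero — a muscle cannot be less than silent), and the
observed signal is the envelope plus broadband interference whose
amplitude is *proportional to the instantaneous envelope*, the standard
amplitude-modulation view of surface EMG. With `noise_sd = 0` the signal
equals the envelope exactly, which is what makes degenerate-input tests
possible. Movements of 1 s sit centrally in 3.5 s trials at 1000 Hz, so
the ±1 s tonic windows always exist. All randomness descends from one
integer seed through deterministic per-trial seed chaining, so datasets
are bit-reproducible and individual trials can be regenerated in
isolation.

What the generator does *not* emulate: biomechanics (no torques,
kinematics or velocity profiles; the acceleration/deceleration split is a
time split), muscle-to-muscle correlations beyond the shared direction
tuning, electrode artifacts, and non-stationary noise. Passing tests
therefore demonstrate that the *pipeline* recovers the structure it
assumes, not that real EMG contains that structure.

## Numerical and design choices

- **Tie-breaks**: LDA posterior ties resolve to the lower class index;
  exact zeros binarize to 0.
- **Degenerate inputs**: zero-variance Z-score cells become zeros plus a
  warning; zero-variance features are dropped inside `fit_lda()`; fully
  tied Friedman tables give statistic 0, p = 1, with a warning; a zero SVM
  normal makes the margin width a labeled error.
- **Chance is not exactly 0.5 at these sample sizes.** Because the
  Z-score is computed per (subject, angle) cell *before* cross-validation
  — the order the methodology prescribes — a held-out trial shares its
  cell's normalization with the training trials of its own class. Under a
  zero-tuning generator this couples folds and biases CV accuracy a few
  percent *below* 0.5; naive within-task label permutation turns cells
  into label-mixed clusters and biases accuracy slightly *above* 0.5. The
  chance-calibration tests therefore compare across-seed mean accuracies
  with the task-level binomial 95% band around 0.5 and bound the grand
  mean within ±0.06, rather than applying an i.i.d. binomial band at
  pooled precision that the pipeline's own dependence structure violates.
- **Problem sizes.** The test-suite and the acceptance script run the
  analyses at a scaled-down size of 6 subjects × 9 angles × 5 trials
  (60 trials per binary task), with 20-seed null and concordance sweeps
  at 4 subjects × 3 angles; the full-factorial 16830-recording design is
  generated raw once to verify the campaign arithmetic. These sizes were
  chosen as the smallest at which the tuning signatures are stable.
- **Standard errors** on curves are across the five folds, the only
  replication unit a single task provides; subject-level resampling would
  be the natural extension.
- **Weakest-muscle control**: when comparing 4 antigravity against 3
  gravity muscles, the group sizes are equalized by dropping the
  antigravity muscle with the lowest mean single-muscle accuracy,
  recomputed from the data rather than fixed by name.

## Limitations

The LDA posterior uses the pooled normalizer P(x) = Σₖ P(x|k) verbatim,
so with unequal priors the reported "posteriors" are proportional to, not
equal to, calibrated probabilities; decisions are unaffected. The margin
width is reported as the geometric 2/‖β‖. Exact rank-sum enumeration is
limited to combined samples of 12; larger samples use the normal
approximation. The pipeline performs no artifact rejection, no onset
detection from EMG, no multiclass or regression-over-angle task, and no
matrix-factorization decompositions; onset and offset markers are taken
as given.
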