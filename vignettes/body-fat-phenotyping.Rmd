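---
title: "Deep-learning body-fat phenotyping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep-learning body-fat phenotyping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Type 2 diabetes is driven less by how much fat a person carries than by
*where* it sits: visceral fat around the abdominal organs is tightly linked
to insulin resistance, while subcutaneous and thigh fat can be metabolically
protective.  Whole-body T1-weighted MRI renders this distribution directly
— adipose tissue is bright, lean tissue dim, air black — so a scan is, in
effect, a 3D map of a person's fat distribution.  `adiponet` implements a
complete analysis around that idea: a multi-task 3D densely connected
convolutional network that reads a standardized whole-body voxel grid and
simultaneously predicts sex, three diabetes-status definitions, age, BMI,
insulin sensitivity and HbA1c; gradients×input attribution to localize
which anatomy drives each prediction; unsupervised subphenotyping of the
network's 128-dimensional scan embeddings; and conventional fat-compartment
benchmark models as the comparison standard.

Clinical whole-body MRI cohorts are rarely shareable, so the package is
organized around a synthetic phantom generator that emulates the
*statistical* structure such an analysis assumes.  Everything downstream
(preprocessing, network, saliency, clustering, survival analysis) treats
the phantoms exactly as it would treat real scans.

# The synthetic cohort model

`generate_phantom()` builds a body as stacked elliptical cross-sections —
head, neck, torso with optional breast bulge, abdomen, pelvis, two legs and
flanking arms — over 90–120 transverse slices (the acquisition-height
range).  Intensities are lean ≈ 0.5, fat = 1.0, air exactly 0, plus mild
Gaussian texture (SD 0.03) inside the body.  Each of seven depot regions
(subcutaneous shell, upper and lower visceral core, thigh, arm, neck,
breast) carries a fat *fraction* in [0, 1]: a seeded smooth random field is
ranked within the region and the darkest-to-brightest `round(fraction ×
region size)` voxels become fat.  Because the field is fixed per seed, fat
sets are nested in the fraction — mean regional intensity and fat extent
are exactly monotone in the depot fraction, and the planted fat-voxel count
is known in closed form (which the compartment-volume tests exploit).  BMI
scales girth as `sqrt(bmi/25)`; sex toggles the shoulder/hip ratio and
breast prominence.

`generate_cohort()` draws labels from a documented generative chain whose
parameters all live in `inst/config/default.yaml`:

1. a latent metabolic class (normoglycemic / prediabetic / diabetic, default
   prevalences 0.50 / 0.25 / 0.25) sets the lower-visceral fat fraction
   (0.20 / 0.50 / 0.80, SD 0.05);
2. insulin sensitivity (Matsuda-like scale) falls with lower-visceral and
   thigh load: `IS = 16 − 10·f_vl − 2·f_thigh + ε`, SD 0.8;
3. fasting glucose, 2h glucose and HbA1c rise linearly in the insulin-
   sensitivity deficit `max(12 − IS, 0)` with independent noise;
4. diagnosis labels then follow mechanically from the clinical thresholds
   (fasting > 7.0 mmol/l strictly, 2h ≥ 11.1 mmol/l, HbA1c ≥ 48 mmol/mol;
   prediabetes from the ADA IFG band 5.6–6.9 and IGT band 7.8–11.0 mmol/l,
   which the source cohort description leaves undefined — both bands are
   configurable);
5. follow-up: exponential event hazards scaled by baseline HbA1c
   (`h0 · exp(β·ΔHbA1c)`), exponential censoring with mean 4.5 years capped
   administratively at 10, chosen to land near a 4 ± 3.7-year mean
   follow-up with event rates of roughly 8% (incident diabetes) and 15%
   (microalbuminuria, threshold uACR ≥ 30 mg/g).

The coefficients in steps 2–4 were calibrated once, analytically, so that
the intended diabetic class crosses the diagnostic thresholds with high
probability and the normoglycemic class essentially never does; realized
Dα prevalence therefore tracks the configured prevalence within binomial
noise.  HbA1c is generated on the % scale and converted with the standard
IFCC relation `mmol/mol = 10.93·pct − 23.5`.

With `signal_mode = "pattern"` the upper-visceral fraction becomes
`1 − f_vl`: diseased and healthy subjects then carry the same expected
total, visceral and upper-extremity fat volumes and differ only in where
*within* the visceral compartment the fat sits.  This is the designed
separation experiment: compartment-volume benchmark models are blind to it
by construction, while the imaging network is not.  (The swap is placed
inside the visceral compartment, not against subcutaneous fat, precisely
because the benchmark features include visceral volume.)

What the phantoms deliberately do **not** model: MR physics (relaxation
times, coil profiles, bias fields, k-space artifacts), organs, realistic
tissue texture, registration error, or repeated scans per subject.  Passing
tests on phantoms therefore demonstrate that the *pipeline machinery*
(normalization, training, attribution, clustering) recovers planted
structure — they say nothing about accuracy on real scanners.

# Grid profiles

Two geometries (`grid_profile()`):

* **paper** — the clinical grid: 90–120 native slices × 150 × 250,
  vertically interpolated to 95 × 150 × 250, downsampled to 85 × 110 × 135.
* **tiny** — the desk-scale default used by the simulations and tests:
  24 × 19 × 31 → 22 × 14 × 17.  The in-plane axes are scaled by ≈ 1/8; the
  vertical axis keeps ≈ 1/4 of its scale.  The asymmetry is deliberate:
  the upper/lower visceral distinction spans about one-tenth of body
  height, and after the network's four stride-2 poolings an 11-slice grid
  cannot represent it at all, whereas 22 slices can.  Training at this
  scale takes seconds per epoch on one CPU; the suite's two training runs
  (n = 300 and n = 220 phantoms, 12 and 10 epochs) finish in under ten
  minutes.

# Preprocessing

`normalize_shape()` linearly interpolates the vertical axis to the target
slice count and then downsamples the whole grid to the final dimensions,
with no further correction of the coarser vertical resolution.
Interpolation is endpoint-aligned trilinear, so resampling to the same
grid is exactly the identity (the pipeline is idempotent at target
dimensions) and a constant-valued body stays exactly constant in its
interior.  An optional Gaussian pre-smoothing flag (`antialias`, default
off) is available for heavily aliased inputs; it is off by default so the
transform stays exactly linear.  Masks travel along with nearest-neighbour
resampling.

`normalize_voxels()` identifies non-body voxels from the intensity
distribution — Otsu's two-class histogram threshold, keeping the largest
6-connected foreground component as the body — sets them exactly to 0,
standardizes body voxels to mean 0 / SD 1, truncates to ±3 SD (the
truncation quantile is not dictated by the reference description; ±3 SD is
a declared choice), and shifts by 3.01 so the body minimum is strictly
positive while air stays at 0, preserving the body/air distinction.  The
standardization statistics default to the scan's own (used by the
single-scan API and the structural tests); the pipeline computes one shared
transform from training-fold body voxels and applies it to every scan
(`voxel_stats: global`), reading "transformed all samples equally" as a
single shared transform.  The returned parameter record makes either
choice exactly reproducible.

`remove_outliers()` is a from-scratch isolation forest (100 trees,
subsample 256, random axis-aligned splits, anomaly score
`2^(−E[h]/c(ψ))`), fit on exactly insulin sensitivity, BMI, HbA1c and the
total adipose-tissue estimate; the top `contamination` fraction (default
5%) is dropped.  No isolation-forest package ships with the environment,
so the algorithm is implemented here and validated on planted extremes.

`normalize_labels()` min–max scales each continuous label with
*training-fold* extrema and retains the inverse transform, so a normalized
MAE converts exactly to an absolute error (`MAE × range`).  Missing labels
are masked per head during training rather than discarding the scan; a
strict whole-row exclusion is a one-line change at the call site.

`stratified_split()` bins BMI and insulin sensitivity into tertiles,
crosses them with diabetes status, merges singleton strata into the nearest
stratum (same status first, then closest bins), and apportions each stratum
over train/validation/test at 70/15/15 with a largest-remainder scheme that
keeps per-stratum allocations within one subject of exact while forcing the
global fold sizes to be exact.  The reference description's stratification
algorithm itself is unavailable; only its constraint (every stratum keeps
more than one subject) is reproduced.

# Augmentation

Training-time transforms, in order: random zero-padding per side (realized
as an integer translation after cropping back to the input grid, default
up to 2 voxels), random rotations (±10° about the vertical axis, ±5° about
the horizontal axes — the rotation magnitudes are declared defaults),
Gaussian noise added to body voxels only (default SD 0.05, i.e. 5% of the
normalized body SD; the background stays exactly 0), and optional ±10%
zoom (off by default, used in sensitivity analyses).  Validation and test
volumes are only centred (body centroid to grid centre, integer shift), a
deterministic and idempotent operation.

`crop_region()` implements the restricted-field-of-view sensitivity
variants by zeroing all slices outside a vertical window: torso
[0.12, 0.56] and abdomen [0.36, 0.56] of the grid axis by default.  The
windows are defined on the grid (not the body extent) so that cropping is
idempotent, and they are matched to the phantom body plan, under which the
torso window excludes legs entirely and the abdomen window keeps both
visceral depots while dropping the neck.  Cropping precedes centring in
the pipeline.  Both windows are configurable.

# The network

`build_model()` assembles, for any input grid:

* initial 5×5×5 convolution (8 filters by default — the reference
  description states both 8 filters and 4 activation maps for this layer;
  8 is the default and `init_filters` exposes the alternative), batch
  normalization, ELU, stride-2 max pooling;
* three dense blocks: each layer is BN → ELU → 3×3×3 convolution producing
  `growth = 18` feature maps concatenated onto its input.  Layers per
  block is not pinned by the reference description; the default is 4,
  chosen to keep tiny-profile training in the minutes range;
* transition layers after each block: BN → ELU → 1×1×1 convolution at
  compression 0.5 → stride-2 average pooling (DenseNet convention; the
  reference names transitions without detail);
* flatten, then fully connected 512 → 256 → 128 with ELU and dropout
  (rate 0.2, a declared default), the 128-vector being the scan embedding;
* heads off the embedding: 2-node softmax per binary label (required so
  that attribution can select the node matching the true label) and a
  single linear unit per regression label.

All weights use He initialization; the parameter count is a pure function
of the configuration.  Training is mini-batch Adam (batch size 8, initial
learning rate 1e-4) under a cyclic exponentially decaying schedule,
`lr(e) = 1e-4 · 0.98^e · (0.5 + 0.25(1 + cos 2πe/20))`, which starts at
exactly the initial rate; the schedule family is prescribed, the decay
0.98 and cycle length 20 are declared here.  The loss is an equally
weighted sum (weights configurable) of per-head cross-entropy and, for
regression, mean absolute error on normalized labels — MAE is both the
reported metric and the training loss, with per-head missing-label
masking.  Validation metrics (AUROC per binary head, normalized MAE per
regression head) are computed once per epoch and a full parameter snapshot
is checkpointed; `select_checkpoint()` takes the highest validation
diabetes AUROC, earliest epoch on ties.  Evaluation mode freezes batch
normalization on running statistics and disables dropout, so inference is
exactly reproducible.

The forward and backward passes are implemented in the package (im2col +
GEMM convolution kernels in C++ via RcppArmadillo, analytic batch-norm and
ELU backpropagation, Adam in R) and are verified against finite-difference
gradients in the test suite to ~1e-6 relative error.

# Attribution

`gradient_x_input()` multiplies each input voxel by the gradient of one
selected output node with respect to that voxel, on the frozen network.
For classification only the node of the *true* label is differentiated
(for a female-labelled scan, only the gradient increasing the female
probability); both gradient signs are kept in the product by default, with
a positive-only switch.  For regression, only positive gradient components
are kept.  Where the input is zero the map is identically zero, and for a
linear model the map is exactly weight ∘ input — both properties are
asserted as exact tests.

`postprocess_heatmap()` smooths with a Gaussian (σ = 2 voxels), clips
magnitudes at the 99th percentile, and averages along the coronal axis for
2D display; σ and the clip quantile are declared defaults since only the
operations themselves are prescribed.

`region_fractions()` mechanizes the expert heatmap rating as an automated
analogue: a map highlights a region when the region contains at least 10%
of the map's top 5% attribution voxels, and the report gives, per region,
the fraction of maps that highlight it.  The criterion is declared and
configurable — human judgment is not reproducible, so the tests assert a
*rank* property (the planted region is the modal highlighted region), not
any printed percentage.

# Embedding clustering and outcomes

Embeddings are all-continuous, so the Gower distance reduces to the mean
of range-normalized absolute differences (ranges from the clustered
sample); the implementation is cross-checked against `cluster::daisy`.
Partitioning around medoids (`cluster::pam`, BUILD + SWAP) runs for
k = 2…8 and average silhouette width selects k; on ≤ 12 points the PAM
solution is checked against exhaustive medoid enumeration.  Cluster
stability is estimated by re-clustering bootstrap resamples at the
selected k and matching each original cluster to its maximum-Jaccard
counterpart (B = 100 by default).  On the generator's default subtype
mixture — four spherical Gaussian subtypes in 128 dimensions, centre SD
1.5, within-subtype SD 0.5, chosen once as a clearly separated mixture —
silhouette selection returns k = 4.

`outcome_analysis()` produces Kaplan–Meier curves per cluster, log-rank
tests and proportional-hazards fits for incident diabetes and incident
microalbuminuria, with the standard adjustment sets (sex + age + BMI;
baseline HbA1c; baseline uACR), and emits scaled Schoenfeld residual
diagnostics (`cox.zph`) for review rather than auto-judgement.  The
log-rank implementation (via `survival::survdiff`) is checked against a
permutation reference within Monte-Carlo error.  Sex-stratified clustering
is available as independent per-stratum runs.

# Benchmarks and metrics

`compartment_volumes()` counts fat voxels (raw intensity ≥ 0.75, midway
between lean and fat) inside the ground-truth masks and converts to litres
via the voxel volume: total (whole body), visceral (upper + lower core)
and upper-extremity (arms).  `fit_benchmarks()` fits the four conventional
families — linear regression (for binary labels the 0/1 response is fit
and the fitted value used as the ranking score), k-nearest neighbours
(k = 5; classification via `class::knn`, regression via a small built-in
neighbour average), random forest (200 trees) and SVM (RBF, probability
outputs) — on exactly the three compartment features, with hyperparameters
fixed at conventional defaults and logged.  AUROC is rank-based with
midrank ties (verified against brute-force pair counting) and is computed
on pooled validation + test rows for the scarce-positive diabetes labels,
as in the reference analysis; MAE converts to absolute units through the
stored inverse transforms.

# Numerical and degenerate-input conventions

* Seeds: every stochastic operation takes an explicit seed and restores
  the caller's RNG state; cohort, split, training, bootstrap and benchmark
  seeds are recorded in the pipeline manifest.
* Silhouette ties select the smallest k; checkpoint ties the earliest
  epoch; pooling uses ceil-mode so no axis collapses below one voxel.
* Degenerate inputs are signalled, not silently repaired: zero-variance
  bodies, constant label columns, single-class AUROC truth, empty training
  folds, misaligned masks, malformed volume files.
* A non-finite training loss aborts the run with the epoch and batch named.

# Problem sizes used by the shipped checks

Simulation and test sizes are chosen so the whole suite is a desk-scale
run: cohorts of 200–1000 subjects for label-model and splitting checks
(labels only), n = 300 and n = 220 phantom cohorts at the tiny profile
with 12 and 10 training epochs for the two signal-recovery runs, 400
embeddings for cluster-number selection, B = 20–100 bootstrap resamples,
and single paper-profile phantoms for the grid-geometry checks.  The
full-scale configuration (85 × 110 × 135 grids, 250 epochs) is expressible
through the same `model_config()`/`grid_profile("paper")` interface but is
a data-centre-GPU-sized computation and is not exercised by the tests.

# Known limitations

* Phantoms are statistical stand-ins; none of the results here transfer
  claims to real MRI.
* The hand-rolled network favours clarity over throughput: single-threaded
  C++ GEMM kernels, no mixed precision, no GPU.
* Sex classification on tiny-profile phantoms is weak (the morphological
  cue survives downsampling only partially); the diabetes heads are the
  calibrated signal path.
* Human-rater heatmap scoring and interrater agreement are out of scope;
  `region_fractions()` is an automated analogue with a declared criterion.
* The bootstrap Jaccard of real embeddings (reported as 0.73 on the
  private cohort) is not a reproducible target; the implementation is
  instead validated on separated vs noise mixtures.
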