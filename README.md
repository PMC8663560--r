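# adiponet

Deep-learning body-fat phenotyping from whole-body MRI volumes.

Whole-body T1-weighted MRI contrasts bright adipose against dim lean
tissue, so a scan is effectively a 3D map of a person's fat distribution —
and the *location* of fat (visceral vs subcutaneous, upper vs lower
abdomen) is what matters for type 2 diabetes risk. `adiponet` implements a
complete, tested pipeline around this idea for researchers in metabolic
imaging:

* a **multi-task 3D DenseNet** (growth factor k = 18, initial 5×5×5
  convolution, 3 dense blocks with BN–ELU–3×3×3 layers, transitions with
  0.5 compression, fully connected 512 → 256 → 128) that reads a
  standardized voxel grid and jointly predicts sex, three diabetes-status
  definitions (Dα diabetes, Dβ prediabetes, Dγ diabetes+IFG+IGT), age,
  BMI, insulin sensitivity and HbA1c, trained with Adam (lr 10⁻⁴, cyclic
  exponential decay, batch 8) under per-head cross-entropy / MAE loss with
  missing-label masking. The penultimate 128-vector is the scan
  **embedding**. Forward and backward passes are implemented in the
  package (im2col+GEMM C++ kernels), verified against finite differences;
* **gradients×input saliency**: per-voxel attribution
  `x · ∂(output node)/∂x` for the true-label node, with Gaussian/contrast
  postprocessing, coronal projection, and an automated anatomical region
  report (fraction of maps highlighting each depot);
* **preprocessing** exactly mirroring the clinical pipeline: vertical
  interpolation of 90–120-slice scans to 95×150×250 and downsampling to
  85×110×135 (paper profile), Otsu-based background zeroing, body-voxel
  standardization to mean 0/SD 1 with ±3 SD truncation and a positive
  shift, isolation-forest outlier removal on four medical features,
  min–max label normalization with training-fold extrema, and a stratified
  70/15/15 split (BMI × insulin-sensitivity tertiles × diabetes status);
* **embedding subphenotyping**: partitioning around medoids on Gower
  distances with silhouette-selected k, bootstrap Jaccard cluster
  stability, Kaplan–Meier / log-rank / proportional-hazards outcome
  analysis for incident diabetes and microalbuminuria;
* **fat-compartment benchmarks** (linear, kNN, random forest, SVM on
  total/visceral/upper-extremity adipose volumes) for the
  network-vs-conventional comparison;
* a **label-conditioned phantom generator**: because such cohorts are
  rarely shareable, the package simulates whole-body phantoms whose depot
  fat fractions are coupled to insulin sensitivity, glycemia and survival
  follow-up, with diagnosis labels derived from the clinical thresholds
  (fasting > 7.0 mmol/l, 2h ≥ 11.1 mmol/l, HbA1c ≥ 48 mmol/mol,
  uACR ≥ 30 mg/g). A `pattern` mode plants the disease signal at matched
  compartment volumes so only imaging — not volumetry — can find it.

See the methods vignette
(`vignettes/body-fat-phenotyping.Rmd`) for the generative model, every
tunable parameter, and the design decisions.

## Worked example

```r
library(adiponet)

## a synthetic cohort: labels follow the documented generative chain
co <- generate_cohort(200, seed = 1, volumes = FALSE)
table(co$labels$Da)
#>   0   1
#> 153  47
cor(co$labels$depot_visceral_lower, co$labels$insulin_sensitivity,
    method = "spearman")
#> [1] -0.92

## one phantom through the preprocessing chain (desk-scale grid)
ph  <- generate_phantom(phantom_spec(seed = 1, bmi = 32, sex = 1,
                                     slice_count = 104))
vol <- normalize_shape(ph, profile = grid_profile("tiny"))
nv  <- normalize_voxels(vol)
dim(nv$voxels); sd(nv$voxels[nv$body_mask])
#> [1] 22 14 17
#> [1] 1
compartment_volumes(ph)
#> $total_adipose_volume            [1] 6.81   # litres
#> $visceral_adipose_volume         [1] 1.16
#> $upper_extremity_adipose_volume  [1] 0.68

## embedding subphenotypes: silhouette-selected PAM on Gower distances
emb <- simulate_embeddings(400, seed = 1)
res <- pam_silhouette(gower_matrix(emb$embeddings), k_range = 2:8)
res
#> <cluster_result> k = 4 | sizes: 100/100/100/100
res$silhouette
#>   k avg_width
#> 1 2     0.367
#> 2 3     0.504
#> 3 4     0.650   <- selected
#> 4 5     0.491
#> 5 6     0.329
#> 6 7     0.166
#> 7 8     0.008
```

The diabetes prevalence (47/200) sits at the configured rate of 0.25; the
strong negative rank correlation is the designed coupling between
lower-visceral fat load and insulin sensitivity; the body voxels have unit
SD with background exactly zero; and average silhouette width is maximal
at four subtypes, the cluster count the method is expected to find on
well-separated embeddings.

An end-to-end run (simulate → preprocess → split → train → select → infer
→ saliency → cluster → evaluate), writing CSV/JSON artifacts and a
manifest to a run directory:

```r
run_pipeline(default_config("tiny"), out_dir = "runs/demo", seed = 1)
```

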