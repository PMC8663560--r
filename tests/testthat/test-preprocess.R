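test_that("shape normalization standardizes the vertical axis then downsamples", {
  ph <- tiny_phantom(seed = 21, slice_count = 112)
  ns <- normalize_shape(ph, profile = grid_profile("tiny"))
  expect_identical(dim(ns$voxels), grid_profile("tiny")$final_dims)
  expect_identical(dim(ns$body_mask), grid_profile("tiny")$final_dims)
  expect_error(normalize_shape(ph, target_dims = c(0, 19, 31),
                               final_dims = c(11, 14, 17)), "positive")
})

test_that("shape normalization is the identity at target dims (idempotent)", {
  ph <- tiny_phantom(seed = 22)
  ns1 <- normalize_shape(ph, profile = grid_profile("tiny"))
  ns2 <- normalize_shape(ns1, target_dims = c(22, 14, 17),
                         final_dims = c(22, 14, 17))
  expect_equal(ns1$voxels, ns2$voxels, tolerance = 1e-12)
})

test_that("linear interpolation of a constant body stays constant inside it", {
  x <- array(0, c(20, 10, 10))
  x[4:16, 3:8, 3:8] <- 2.5
  v <- list(voxels = x)
  ns <- normalize_shape(v, target_dims = c(12, 10, 10),
                        final_dims = c(12, 10, 10))
  inner <- ns$voxels[5:8, 5:6, 5:6]   # strictly interior of the body
  expect_true(all(abs(inner - 2.5) < 1e-12))
})

test_that("shape normalization preserves body topology on phantoms", {
  ph <- tiny_phantom(seed = 23)
  ns <- normalize_shape(ph, profile = grid_profile("tiny"))
  # the resampled body mask stays a single dominant connected component
  lab <- adiponet:::cpp_label_components(as.logical(ns$body_mask),
                                         dim(ns$body_mask))
  sizes <- table(lab[lab > 0])
  expect_gt(max(sizes) / sum(sizes), 0.95)
})

test_that("voxel normalization: unit body SD, positive body, zero background", {
  ns <- normalize_shape(tiny_phantom(seed = 24), profile = grid_profile("tiny"))
  nv <- normalize_voxels(ns)
  body <- nv$body_mask
  expect_equal(sd(nv$voxels[body]), 1, tolerance = 1e-6)
  expect_equal(mean(nv$voxels[body]) - nv$voxel_params$shift, 0,
               tolerance = 1e-9)
  expect_gt(min(nv$voxels[body]), 0)
  expect_true(all(nv$voxels[!body] == 0))
  # determinism: two copies of the same scan transform identically
  nv2 <- normalize_voxels(ns)
  expect_identical(nv$voxels, nv2$voxels)
})

test_that("voxel normalization statistics come from body voxels only", {
  ns <- normalize_shape(tiny_phantom(seed = 25), profile = grid_profile("tiny"))
  nv <- normalize_voxels(ns)
  raw_body <- ns$voxels[nv$body_mask]
  expect_equal(nv$voxel_params$mean, mean(raw_body))
  expect_equal(nv$voxel_params$sd, sd(raw_body))
})

test_that("a shared training-fold transform is applied equally to all scans", {
  vs <- lapply(c(31, 32), function(s)
    normalize_shape(tiny_phantom(seed = s), profile = grid_profile("tiny")))
  stats <- compute_body_stats(lapply(vs, `[[`, "voxels"))
  n1 <- normalize_voxels(vs[[1]], stats = stats)
  n2 <- normalize_voxels(vs[[2]], stats = stats)
  expect_equal(n1$voxel_params$mean, n2$voxel_params$mean)
  expect_equal(n1$voxel_params$sd, n2$voxel_params$sd)
})

test_that("degenerate zero-variance bodies are signalled", {
  x <- array(0, c(8, 8, 8)); x[3:6, 3:6, 3:6] <- 1
  expect_error(normalize_voxels(x), "zero-variance")
})

test_that("isolation forest flags a gross outlier and honours contamination", {
  ft <- data.frame(insulin_sensitivity = c(10, 11, 12, 10.5, 11.5, 9.8, 10.2),
                   bmi = c(25, 26, 27, 25.5, 26.5, 24.8, 25.2),
                   hba1c = c(5.3, 5.4, 5.5, 5.35, 5.45, 5.25, 5.5),
                   total_adipose_volume = c(20, 21, 22, 20.5, 21.5, 19.8, 20.2))
  extreme <- data.frame(insulin_sensitivity = 1000, bmi = 2500, hba1c = 530,
                        total_adipose_volume = 2000)
  tab <- rbind(ft, extreme)
  scores <- isolation_forest_scores(as.matrix(tab), seed = 4)
  # the planted extreme isolates earliest: highest anomaly score
  expect_identical(which.max(scores), nrow(tab))
  keep <- remove_outliers(tab, contamination = 1 / nrow(tab), seed = 4)
  expect_false(keep[nrow(tab)])
  expect_true(all(keep[-nrow(tab)]))
  # contamination 0 keeps every row
  expect_true(all(remove_outliers(tab, contamination = 0)))
  # exchangeable inputs: never drops more than the contamination fraction
  same <- ft[rep(1, 40), ]
  expect_lte(sum(!remove_outliers(same, contamination = 0.1, seed = 1)), 4)
  expect_error(remove_outliers(ft[, -1]), "missing feature")
})

test_that("isolation scores match the expected path-length ordering on tiny data", {
  # 1-D essence: one far point among a tight cluster must have a shorter
  # average isolation path than any cluster member (checked via the score
  # monotonicity score = 2^(-E[h]/c))
  x <- cbind(c(0.0, 0.1, 0.05, 0.12, 0.07, 0.02, 0.09, 100),
             c(0.0, 0.1, 0.05, 0.12, 0.07, 0.02, 0.09, 100),
             c(0.0, 0.1, 0.05, 0.12, 0.07, 0.02, 0.09, 100),
             c(0.0, 0.1, 0.05, 0.12, 0.07, 0.02, 0.09, 100))
  s <- isolation_forest_scores(x, ntrees = 200, seed = 2)
  expect_gt(s[8], max(s[1:7]) + 0.1)
})

test_that("label normalization scales by training extrema and masks missing", {
  lab <- data.frame(id = 1:3, bmi = c(20, 40, 60))
  nl <- normalize_labels(lab, "bmi", train_idx = 1:3)
  expect_equal(nl$labels$bmi, c(0, 0.5, 1))
  # inverse transform round trip: absolute MAE = normalized MAE * range
  expect_equal(nl$denormalize(0.25, "bmi"), 30, ignore_attr = TRUE)
  lab2 <- data.frame(id = 1:4, age = c(30, NA, 50, 70))
  nl2 <- normalize_labels(lab2, "age", train_idx = c(1, 3, 4))
  expect_identical(unname(nl2$mask[, "age"]), c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(nl2$labels$age[c(1, 3, 4)], c(0, 0.5, 1))
  expect_error(normalize_labels(data.frame(id = 1, z = c(2, 2)), "z"),
               "constant")
})

test_that("stratified split honours fold sizes and per-stratum proportions", {
  co <- generate_cohort(1000, seed = 55, volumes = FALSE)
  sp <- stratified_split(co$labels, seed = 9)
  expect_identical(as.integer(table(sp$fold)[c("train", "validation", "test")]),
                   c(700L, 150L, 150L))
  # per-stratum counts within one subject of the exact fractions
  for (s in unique(sp$stratum)) {
    idx <- sp$stratum == s
    ns <- sum(idx)
    cnt <- table(factor(sp$fold[idx],
                        levels = c("train", "validation", "test")))
    expect_true(all(abs(cnt - ns * c(0.7, 0.15, 0.15)) <= 1))
    expect_gt(ns, 1)   # no singleton strata survive merging
  }
})

test_that("split is deterministic per seed with seed-invariant fold sizes", {
  co <- generate_cohort(400, seed = 56, volumes = FALSE)
  s1 <- stratified_split(co$labels, seed = 1)
  s2 <- stratified_split(co$labels, seed = 1)
  s3 <- stratified_split(co$labels, seed = 2)
  expect_identical(s1, s2)
  expect_false(identical(s1$fold, s3$fold))
  expect_identical(table(s1$fold), table(s3$fold))
  expect_error(stratified_split(co$labels, fractions = c(0.5, 0.2, 0.2)),
               "sum to 1")
})

test_that("a single stratum still honours the target fractions", {
  lab <- data.frame(id = 1:200, bmi = 25, insulin_sensitivity = 10, Da = 0L)
  sp <- stratified_split(lab, seed = 3)
  expect_identical(as.integer(table(sp$fold)[c("train", "validation", "test")]),
                   c(140L, 30L, 30L))
})
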