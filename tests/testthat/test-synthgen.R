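test_that("phantom generation is deterministic and respects its invariants", {
  ph1 <- generate_phantom(phantom_spec(seed = 7), grid_profile("tiny"))
  ph2 <- generate_phantom(phantom_spec(seed = 7), grid_profile("tiny"))
  expect_identical(ph1$voxels, ph2$voxels)
  expect_identical(ph1$region_masks, ph2$region_masks)
  # voxels outside the body are exactly zero, body strictly positive
  expect_true(all(ph1$voxels[!ph1$body_mask] == 0))
  expect_gt(min(ph1$voxels[ph1$body_mask]), 0)
  # region masks are pairwise disjoint subsets of the body
  rs <- ph1$region_masks
  for (i in seq_along(rs)) {
    expect_true(all(ph1$body_mask[rs[[i]]]))
    for (j in seq_along(rs)) if (j > i)
      expect_false(any(rs[[i]] & rs[[j]]))
  }
  expect_lte(sum(sapply(rs, sum)), sum(ph1$body_mask))
})

test_that("slice counts outside the 90-120 acquisition range are rejected", {
  expect_error(phantom_spec(slice_count = 89), "slice_count")
  expect_error(phantom_spec(slice_count = 121), "slice_count")
  expect_silent(phantom_spec(slice_count = 90))
  expect_silent(phantom_spec(slice_count = 120))
})

test_that("BMI scales body girth monotonically", {
  lo <- generate_phantom(phantom_spec(seed = 5, bmi = 25), grid_profile("tiny"))
  hi <- generate_phantom(phantom_spec(seed = 5, bmi = 35), grid_profile("tiny"))
  expect_gt(sum(hi$body_mask), sum(lo$body_mask))
})

test_that("depot fraction raises mean intensity inside its region, same seed", {
  df <- default_depot_fractions()
  df["visceral_lower"] <- 0.2
  lo <- generate_phantom(phantom_spec(seed = 9, depot_fractions = df),
                         grid_profile("tiny"))
  df["visceral_lower"] <- 0.8
  hi <- generate_phantom(phantom_spec(seed = 9, depot_fractions = df),
                         grid_profile("tiny"))
  m <- lo$region_masks$visceral_lower
  expect_gt(mean(hi$voxels[m]), mean(lo$voxels[m]))
  # fat placement is nested, so the planted fat-voxel count is exact
  expect_identical(sum(hi$voxels[m] > 0.75), as.integer(round(0.8 * sum(m))))
})

test_that("diagnosis thresholds follow the clinical definitions exactly", {
  # fasting criterion is strictly > 7.0; 2h and HbA1c are inclusive
  expect_equal(assign_diagnosis(7.2, 8.0, 40)$Da, 1L)
  expect_equal(assign_diagnosis(7.0, 8.0, 40)$Da, 0L)
  expect_equal(assign_diagnosis(5.0, 12.0, 40)$Da, 1L)
  expect_equal(assign_diagnosis(5.0, 11.1, 40)$Da, 1L)
  expect_equal(assign_diagnosis(5.0, 8.0, 48)$Da, 1L)
  d <- assign_diagnosis(4.8, 6.5, 30)
  expect_equal(unlist(d), c(Da = 0L, Db = 0L, Dg = 0L))
  expect_error(assign_diagnosis(-1, 8, 40), "nonnegative")
})

test_that("diagnosis logic matches a brute-force re-implementation on a grid", {
  grid <- expand.grid(f = seq(4, 8, by = 0.25),
                      g = seq(5, 12, by = 0.5),
                      h = seq(30, 55, by = 2.5))
  got <- assign_diagnosis(grid$f, grid$g, grid$h)
  for (i in seq_len(nrow(grid))) {
    da <- grid$f[i] > 7.0 || grid$g[i] >= 11.1 || grid$h[i] >= 48
    ifg <- grid$f[i] >= 5.6 && grid$f[i] <= 6.9
    igt <- grid$g[i] >= 7.8 && grid$g[i] <= 11.0
    expect_identical(got$Da[i], as.integer(da))
    expect_identical(got$Db[i], as.integer(!da && (ifg || igt)))
    expect_identical(got$Dg[i], as.integer(da || (ifg && igt)))
  }
  # closure: Da = 1 implies Dg = 1 and Db = 0
  expect_true(all(got$Dg[got$Da == 1] == 1))
  expect_true(all(got$Db[got$Da == 1] == 0))
})

test_that("microalbuminuria threshold is inclusive at 30 mg/g", {
  expect_identical(assign_microalbuminuria(30.0), 1L)
  expect_identical(assign_microalbuminuria(29.9), 0L)
  expect_identical(assign_microalbuminuria(0), 0L)
  expect_error(assign_microalbuminuria(-1), "nonnegative")
})

test_that("HbA1c percent/mmol-per-mol conversion is the standard relation", {
  expect_equal(hba1c_pct_to_mmolmol(hba1c_mmolmol_to_pct(48)), 48)
  expect_equal(hba1c_mmolmol_to_pct(48), 6.54, tolerance = 0.01)
})

test_that("cohort diabetes prevalence matches the configured rate", {
  co <- generate_cohort(200, seed = 31, volumes = FALSE)
  p_cfg <- default_label_model()$prevalence$diabetes
  ci <- stats::binom.test(sum(co$labels$Da), 200)$conf.int
  expect_true(p_cfg >= ci[1] && p_cfg <= ci[2])
})

test_that("with zero noise SDs glycemia is a deterministic function of depots", {
  lm0 <- default_label_model()
  lm0$depots$sd <- 0
  lm0$insulin$sd <- 0
  lm0$glycemia$fasting$sd <- 0
  lm0$glycemia$g2h$sd <- 0
  lm0$glycemia$hba1c$sd <- 0
  co1 <- generate_cohort(50, config = lm0, seed = 1, volumes = FALSE)
  co2 <- generate_cohort(50, config = lm0, seed = 2, volumes = FALSE)
  # same depot fractions must give the same glycemia across different draws
  f <- function(co) {
    g <- lm0$glycemia
    ins <- lm0$insulin
    is_val <- pmax(ins$base - ins$visc_coef * co$labels$depot_visceral_lower -
                     ins$thigh_coef * co$labels$depot_thigh, 0.5)
    defi <- pmax(ins$deficit_ref - is_val, 0)
    pmax(g$fasting$base + g$fasting$coef * defi, 2.5)
  }
  expect_equal(co1$labels$fasting_glucose, f(co1))
  expect_equal(co2$labels$fasting_glucose, f(co2))
})

test_that("cohort generation is seed-deterministic and couples depots to labels", {
  co1 <- generate_cohort(250, seed = 77, volumes = FALSE)
  co2 <- generate_cohort(250, seed = 77, volumes = FALSE)
  expect_identical(co1$labels, co2$labels)
  expect_identical(co1$followup, co2$followup)
  # configured negative coupling between lower-visceral load and insulin
  # sensitivity is recovered
  rho <- cor(co1$labels$depot_visceral_lower,
             co1$labels$insulin_sensitivity, method = "spearman")
  expect_lt(rho, -0.5)
  expect_error(generate_cohort(0), "n must be")
})

test_that("follow-up records are consistent survival data", {
  co <- generate_cohort(300, seed = 13, volumes = FALSE)
  fu <- co$followup
  expect_true(all(fu$time_to_diabetes >= 0))
  expect_true(all(fu$diabetes_event %in% 0:1))
  expect_true(all(fu$time_to_diabetes <= 10))
  expect_true(all(fu$microalbuminuria_baseline ==
                    (fu$baseline_uacr >= 30)))
  # mean follow-up in the ballpark of the 4 +/- 3.7 year design
  expect_gt(mean(fu$time_to_diabetes), 2)
  expect_lt(mean(fu$time_to_diabetes), 6)
})

test_that("embedding mixture is deterministic with separated subtypes", {
  e1 <- simulate_embeddings(100, seed = 5)
  e2 <- simulate_embeddings(100, seed = 5)
  expect_identical(e1$embeddings, e2$embeddings)
  expect_identical(dim(e1$embeddings), c(100L, 128L))
  # within-subtype distances are smaller than between-subtype distances
  d <- as.matrix(dist(e1$embeddings))
  same <- outer(e1$subtype, e1$subtype, `==`)
  diag(same) <- NA
  expect_lt(max(d[which(same)], na.rm = TRUE),
            min(d[which(!same)], na.rm = TRUE))
})
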