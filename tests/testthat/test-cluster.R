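test_that("Gower distance follows its definition on hand-checked cases", {
  d <- gower_matrix(matrix(c(0, 5, 10), ncol = 1))
  expect_equal(d[1, 3], 1)
  expect_equal(d[1, 2], 0.5)
  x <- matrix(rnorm(40), 10, 4)
  x[2, ] <- x[1, ]
  D <- gower_matrix(x)
  expect_equal(D[1, 2], 0)
  expect_true(all(D >= 0 & D <= 1))
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  # cross-check against the reference mixed-type implementation
  ref <- as.matrix(cluster::daisy(as.data.frame(x), metric = "gower"))
  expect_equal(D, ref, ignore_attr = TRUE, tolerance = 1e-12)
  expect_warning(gower_matrix(cbind(x, 1)), "zero-range")
  expect_error(gower_matrix(x[1, , drop = FALSE]), "at least 2")
})

test_that("silhouette-selected PAM recovers well-separated groups", {
  emb <- simulate_embeddings(120, k = 4, seed = 3)
  d <- gower_matrix(emb$embeddings)
  res <- pam_silhouette(d, 2:8)
  expect_identical(res$k, 4L)
  # perfect recovery of the subtype partition
  expect_equal(length(unique(paste(res$assignments, emb$subtype))), 4L)
  expect_true(all(res$assignments[res$medoids] == seq_len(4)))
  expect_error(pam_silhouette(d, k_range = c(1, 3)), "k_range")
  expect_error(pam_silhouette(gower_matrix(matrix(rnorm(4), 2, 2)), 2),
               "at least 3")
})

test_that("PAM solution matches exhaustive medoid search on small inputs", {
  for (seed in 1:3) {
    set.seed(seed)
    x <- matrix(rnorm(24), 12, 2)
    d <- gower_matrix(x)
    for (k in 2:3) {
      fit <- cluster::pam(as.dist(d), k, diss = TRUE)
      expect_equal(pam_cost(d, fit$id.med), exhaustive_medoid_cost(d, k),
                   tolerance = 1e-12)
    }
  }
})

test_that("duplicated points per group give silhouette width 1 in the separated limit", {
  x <- rbind(matrix(0, 2, 3), matrix(10, 2, 3), matrix(20, 2, 3))
  x <- x + 0   # exact duplicates within groups
  d <- gower_matrix(jitter_free <- x)
  res <- pam_silhouette(d, 2:4)
  expect_identical(res$k, 3L)
  expect_equal(res$silhouette$avg_width[res$silhouette$k == 3], 1)
})

test_that("bootstrap stability is maximal for separated data, lower for noise", {
  emb <- simulate_embeddings(60, k = 3, seed = 9)
  d <- gower_matrix(emb$embeddings)
  res <- pam_silhouette(d, 2:5)
  st <- bootstrap_stability(d, res, B = 20, seed = 4)
  expect_equal(unname(st$overall), 1)
  expect_true(all(st$per_cluster == 1))
  set.seed(11)
  noise <- matrix(rnorm(60 * 8), 60, 8)
  dn <- gower_matrix(noise)
  resn <- pam_silhouette(dn, 3:3)
  stn <- bootstrap_stability(dn, resn, B = 20, seed = 4)
  expect_lt(stn$overall, st$overall)
  expect_error(bootstrap_stability(d, res, B = 0), "B must be")
})

test_that("log-rank agrees with a permutation reference on a small cohort", {
  set.seed(21)
  n <- 40
  fu <- data.frame(time = rexp(n, 0.2), ev = rbinom(n, 1, 0.7))
  cl <- rep(1:2, each = n / 2)
  obs <- survival::survdiff(survival::Surv(time, ev) ~ cl, data = fu)
  perm <- replicate(500, {
    survival::survdiff(survival::Surv(time, ev) ~ sample(cl), data = fu)$chisq
  })
  p_perm <- mean(perm >= obs$chisq)
  p_chisq <- 1 - pchisq(obs$chisq, 1)
  expect_lt(abs(p_perm - p_chisq), 3 * sqrt(p_chisq * (1 - p_chisq) / 500) + 0.02)
})

test_that("outcome analysis separates a high-hazard cluster", {
  set.seed(22)
  n <- 240
  cl <- rep(1:3, each = n / 3)
  haz <- ifelse(cl == 3, 0.45, 0.15)
  td <- rexp(n, haz); cd <- pmin(10, rexp(n, 1 / 5))
  fu <- data.frame(
    time_to_diabetes = pmin(td, cd), diabetes_event = as.integer(td <= cd),
    time_to_microalbuminuria = pmin(td, cd),
    microalbuminuria_event = as.integer(td <= cd),
    baseline_uacr = rlnorm(n, log(8), 0.5))
  cov <- data.frame(sex = rbinom(n, 1, 0.5), age = rnorm(n, 50, 8),
                    bmi = rnorm(n, 27, 3), hba1c = rnorm(n, 5.5, 0.3))
  oc <- outcome_analysis(cl, fu, cov)
  expect_lt(oc$diabetes$logrank$p, 0.01)
  hr <- coef(oc$diabetes$cox$unadjusted)
  expect_gt(hr["cluster3"], max(0, hr["cluster2"]))
  # adjusted models keep the cluster effect (hazards differ by design)
  expect_gt(coef(oc$diabetes$cox$demographics)["cluster3"], 0)
  expect_error(outcome_analysis(cl[-1], fu, cov), "aligned")
})

test_that("all-censored data yield a flat Kaplan-Meier curve and a warning", {
  n <- 30
  fu <- data.frame(time_to_diabetes = rep(5, n), diabetes_event = 0L,
                   time_to_microalbuminuria = rep(5, n),
                   microalbuminuria_event = 0L,
                   baseline_uacr = rep(8, n))
  cov <- data.frame(sex = rbinom(n, 1, 0.5), age = rnorm(n, 50),
                    bmi = rnorm(n, 27), hba1c = rnorm(n, 5.5, 0.2))
  ws <- capture_warnings(oc <- outcome_analysis(rep(1:2, n / 2), fu, cov))
  expect_true(any(grepl("no events", ws)))
  expect_true(all(summary(oc$diabetes$km)$surv == 1))
})

test_that("two clusters with identical event processes show no log-rank signal", {
  set.seed(23)
  n <- 200
  td <- rexp(n, 0.2); cd <- pmin(10, rexp(n, 1 / 5))
  fu <- data.frame(time_to_diabetes = pmin(td, cd),
                   diabetes_event = as.integer(td <= cd),
                   time_to_microalbuminuria = pmin(td, cd),
                   microalbuminuria_event = as.integer(td <= cd),
                   baseline_uacr = rlnorm(n, log(8), 0.5))
  cov <- data.frame(sex = rbinom(n, 1, 0.5), age = rnorm(n, 50),
                    bmi = rnorm(n, 27), hba1c = rnorm(n, 5.5, 0.2))
  oc <- outcome_analysis(rep(1:2, each = n / 2), fu, cov)
  expect_gt(oc$diabetes$logrank$p, 0.05)
  expect_lt(oc$diabetes$logrank$chisq, 3.9)
})
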