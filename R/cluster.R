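#' Gower distance matrix for continuous embeddings
#'
#' For all-continuous features the Gower distance reduces to the mean over
#' dimensions of range-normalized absolute differences, so every entry lies
#' in \[0,1\] with a zero diagonal.  Ranges are computed on the clustered
#' sample; zero-range dimensions are dropped with a warning.
#'
#' @param embeddings numeric matrix (n x p), no missing values.
#' @return symmetric n x n distance matrix.
#' @export
gower_matrix <- function(embeddings) {
  x <- as.matrix(embeddings)
  if (nrow(x) < 2) stop("need at least 2 observations")
  if (anyNA(x)) stop("missing values are not supported")
  rng <- apply(x, 2, function(v) diff(range(v)))
  keep <- rng > 0
  if (!all(keep)) {
    warning(sum(!keep), " zero-range dimension(s) dropped")
    x <- x[, keep, drop = FALSE]
    rng <- rng[keep]
  }
  if (!ncol(x)) stop("no informative dimensions left")
  xs <- sweep(x, 2, rng, `/`)
  as.matrix(dist(xs, method = "manhattan")) / ncol(x)
}

#' Partitioning around medoids with silhouette-based k selection
#'
#' Runs PAM (BUILD + SWAP, via `cluster::pam`) on a precomputed distance
#' matrix for every k in `k_range` and selects the k with the largest
#' average silhouette width (ties broken toward smaller k).
#'
#' @param dist distance matrix (e.g. from [gower_matrix()]).
#' @param k_range candidate cluster counts, each within \[2, n-1\].
#' @param seed retained for interface symmetry; PAM BUILD+SWAP is
#'   deterministic on a fixed distance matrix.
#' @return A `cluster_result`: `k`, `assignments`, `medoids` (indices),
#'   `silhouette` (data.frame k / avg_width), per-point `sil_widths`.
#' @export
pam_silhouette <- function(dist, k_range = 2:8, seed = 1L) {
  d <- as.matrix(dist)
  n <- nrow(d)
  if (n < 3) stop("need at least 3 observations")
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2 | k_range > n - 1))
    stop("k_range must lie within [2, n-1]")
  fits <- list()
  widths <- numeric(length(k_range))
  for (i in seq_along(k_range)) {
    fit <- cluster::pam(as.dist(d), k_range[i], diss = TRUE)
    fits[[i]] <- fit
    widths[i] <- fit$silinfo$avg.width
  }
  best <- which.max(widths)   # first max = smallest k on ties
  fit <- fits[[best]]
  structure(list(k = k_range[best],
                 assignments = as.integer(fit$clustering),
                 medoids = as.integer(fit$id.med),
                 silhouette = data.frame(k = k_range, avg_width = widths),
                 sil_widths = fit$silinfo$widths),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result> k =", x$k, "| sizes:",
      paste(table(x$assignments), collapse = "/"), "\n")
  invisible(x)
}

#' Bootstrap cluster stability (Jaccard indices)
#'
#' Re-clusters bootstrap resamples (at the selected k) and matches each
#' original cluster to its maximum-Jaccard counterpart; reports the mean
#' Jaccard index per cluster and overall.  Values near 1 indicate highly
#' reproducible clusters.
#'
#' @param dist distance matrix used for the original clustering.
#' @param result a `cluster_result`.
#' @param B number of bootstrap resamples.
#' @param seed integer.
#' @return list with `per_cluster`, `overall`, `B`.
#' @export
bootstrap_stability <- function(dist, result, B = 100, seed = 1L) {
  if (B < 1) stop("B must be >= 1")
  d <- as.matrix(dist)
  n <- nrow(d)
  k <- result$k
  jac <- matrix(NA_real_, B, k)
  with_rng_seed(seed, {
    for (b in seq_len(B)) {
      take <- sort(unique(sample.int(n, n, replace = TRUE)))
      cl <- if (length(take) > k)
        cluster::pam(as.dist(d[take, take]), k, diss = TRUE)$clustering
      else rep(seq_len(k), length.out = length(take))
      for (ci in seq_len(k)) {
        orig <- intersect(which(result$assignments == ci), take)
        if (!length(orig)) next
        jac[b, ci] <- max(vapply(seq_len(k), function(cj) {
          boot <- take[cl == cj]
          length(intersect(orig, boot)) / length(union(orig, boot))
        }, numeric(1)))
      }
    }
  })
  per_cluster <- colMeans(jac, na.rm = TRUE)
  list(per_cluster = per_cluster, overall = mean(per_cluster), B = B)
}

#' Survival outcome analysis of embedding clusters
#'
#' Kaplan--Meier curves per cluster, log-rank tests and proportional-hazards
#' models for incident diabetes and incident microalbuminuria, with the
#' standard adjustment sets: demographics (sex + age + BMI), baseline
#' glycated hemoglobin (diabetes endpoint), and baseline uACR
#' (microalbuminuria endpoint).  Proportionality is checked with scaled
#' Schoenfeld residuals (`survival::cox.zph`), emitted as a diagnostic.
#'
#' @param assignments integer cluster per subject.
#' @param followup data.frame as produced by [generate_cohort()]:
#'   `time_to_diabetes`, `diabetes_event`, `time_to_microalbuminuria`,
#'   `microalbuminuria_event`, `baseline_uacr`.
#' @param covariates data.frame with `sex`, `age`, `bmi`, `hba1c` aligned
#'   with `assignments`.
#' @return nested list per endpoint: `km` (survfit), `logrank`
#'   (chisq, df, p), `cox` (unadjusted + adjusted fits), `zph`.
#' @export
outcome_analysis <- function(assignments, followup, covariates) {
  if (length(assignments) != nrow(followup))
    stop("assignments and follow-up table are not aligned")
  cl <- factor(assignments)
  if (nlevels(cl) < 2) stop("need at least 2 clusters")
  endpoints <- list(
    diabetes = list(time = "time_to_diabetes", event = "diabetes_event",
                    extra_adjust = "hba1c"),
    microalbuminuria = list(time = "time_to_microalbuminuria",
                            event = "microalbuminuria_event",
                            extra_adjust = "log_uacr"))
  df <- cbind(followup, covariates, cluster = cl)
  df$log_uacr <- log(pmax(followup$baseline_uacr, 1e-6))
  out <- list()
  for (ep in names(endpoints)) {
    e <- endpoints[[ep]]
    if (sum(df[[e$event]]) == 0) {
      warning("no events for endpoint ", ep)
    }
    sv <- survival::Surv(df[[e$time]], df[[e$event]])
    km <- survival::survfit(sv ~ cluster, data = df)
    lr <- survival::survdiff(sv ~ cluster, data = df)
    p <- 1 - stats::pchisq(lr$chisq, length(lr$n) - 1)
    fits <- list(
      unadjusted = survival::coxph(sv ~ cluster, data = df),
      demographics = survival::coxph(sv ~ cluster + sex + age + bmi,
                                     data = df))
    fits[[e$extra_adjust]] <-
      survival::coxph(as.formula(paste("sv ~ cluster +", e$extra_adjust)),
                      data = df)
    zph <- tryCatch(survival::cox.zph(fits$unadjusted),
                    error = function(err) NULL)
    out[[ep]] <- list(km = km,
                      logrank = list(chisq = lr$chisq,
                                     df = length(lr$n) - 1, p = p),
                      cox = fits, zph = zph)
  }
  out
}
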