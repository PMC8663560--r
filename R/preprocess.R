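#' Shape-normalize a body volume
#'
#' Two-stage grid standardization: the vertical (slice) axis is linearly
#' interpolated to the target slice count (95 in the paper-scale profile,
#' matching the most frequent acquisition height) while in-plane dimensions
#' are already standard; the whole grid is then downsampled to the final
#' network input dimensions.  The coarser vertical resolution receives no
#' further interpolation correction.  Body and region masks are carried
#' along with nearest-neighbour resampling.
#'
#' @param volume a `body_volume` (or any list with a `voxels` array).
#' @param target_dims,final_dims integer triples; default from `profile`.
#' @param profile a [grid_profile()] supplying the defaults.
#' @param antialias Gaussian pre-smoothing on downsampled axes (default off,
#'   keeping interpolation exactly linear).
#' @return The volume with `voxels`/masks replaced by fixed-dimension grids
#'   and a `shape_params` record.
#' @export
normalize_shape <- function(volume, target_dims = NULL, final_dims = NULL,
                            profile = grid_profile("tiny"),
                            antialias = FALSE) {
  target_dims <- as.integer(target_dims %||% profile$target_dims)
  final_dims <- as.integer(final_dims %||% profile$final_dims)
  if (any(target_dims <= 0) || any(final_dims <= 0))
    stop("target and final dimensions must be positive")
  x <- volume$voxels
  if (dim(x)[1] < 2) stop("need at least 2 slices along the vertical axis")
  # stage 1: vertical interpolation only (in-plane dims are already standard)
  stage1 <- c(target_dims[1], dim(x)[2], dim(x)[3])
  x1 <- resize_volume(x, stage1, antialias = FALSE)
  # stage 2: downsample everything to the final grid
  x2 <- resize_volume(x1, final_dims, antialias = antialias)
  out <- volume
  out$voxels <- x2
  if (!is.null(volume$body_mask))
    out$body_mask <- resize_mask(volume$body_mask, final_dims)
  if (!is.null(volume$region_masks))
    out$region_masks <- lapply(volume$region_masks, resize_mask, final_dims)
  out$shape_params <- list(source_dims = dim(x), target_dims = target_dims,
                           final_dims = final_dims, antialias = antialias)
  out
}

# Otsu's two-class histogram threshold.
otsu_threshold <- function(x, nbins = 256) {
  r <- range(x)
  if (diff(r) == 0) return(r[1])
  br <- seq(r[1], r[2], length.out = nbins + 1)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[nbins]
  sb <- (mu_t * w0 - mu0)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- 0
  br[which.max(sb) + 1]
}

#' Pooled body-voxel statistics across volumes
#'
#' Mean and SD over the body voxels of a set of scans (typically the
#' training fold), for use as a shared standardization transform so that all
#' scans are transformed equally.
#' @param volumes list of volumes (arrays or `body_volume`s).
#' @return list with `mean` and `sd`.
#' @export
compute_body_stats <- function(volumes) {
  vals <- unlist(lapply(volumes, function(v) {
    x <- if (is.list(v)) v$voxels else v
    mask <- detect_body(x)
    x[mask]
  }))
  list(mean = mean(vals), sd = sd(vals))
}

# Background identification: Otsu threshold on the intensity distribution,
# keep the largest connected foreground component as the body.
detect_body <- function(x) {
  thr <- otsu_threshold(as.numeric(x))
  fg <- x > thr
  if (!any(fg)) return(fg)
  largest_component(fg)
}

#' Voxel-value normalization
#'
#' Sets non-body voxels (identified from the intensity distribution by Otsu
#' thresholding + largest connected component) exactly to 0, standardizes
#' body voxels to mean 0 / SD 1 using `stats` (the scan's own statistics when
#' `stats = NULL`, or a shared training-fold transform from
#' [compute_body_stats()]), truncates to a symmetric `trunc_sd` band, and
#' shifts so the body minimum is strictly positive while air stays at 0.
#'
#' @param volume `body_volume` or bare 3D array.
#' @param stats optional list(mean, sd); `NULL` = per-scan statistics.
#' @param trunc_sd symmetric truncation band in SD units.
#' @param shift_eps the body minimum after shifting is at least this.
#' @return The volume with transformed `voxels`, the detected `body_mask`,
#'   and a `voxel_params` record of the transform for exact reuse.
#' @export
normalize_voxels <- function(volume, stats = NULL, trunc_sd = 3,
                             shift_eps = 0.01) {
  bare <- !is.list(volume)
  x <- if (bare) volume else volume$voxels
  body <- detect_body(x)
  if (!any(body)) stop("no body voxels detected")
  vals <- x[body]
  if (sd(vals) == 0) stop("degenerate input: zero-variance body")
  mu <- if (is.null(stats)) mean(vals) else stats$mean
  sg <- if (is.null(stats)) sd(vals) else stats$sd
  z <- (vals - mu) / sg
  z <- pmin(pmax(z, -trunc_sd), trunc_sd)
  out <- array(0, dim(x))
  out[body] <- z + trunc_sd + shift_eps
  params <- list(mean = mu, sd = sg, trunc_sd = trunc_sd,
                 shift = trunc_sd + shift_eps,
                 per_scan = is.null(stats))
  if (bare) return(structure(list(voxels = out, body_mask = body,
                                  voxel_params = params),
                             class = "body_volume"))
  volume$voxels <- out
  volume$body_mask <- body
  volume$voxel_params <- params
  volume
}

# ---- isolation forest ------------------------------------------------------

# Average unsuccessful-search path length in a binary search tree of size n.
iforest_cn <- function(n) {
  if (n <= 1) return(0)
  2 * (log(n - 1) + 0.5772156649) - 2 * (n - 1) / n
}

iforest_tree <- function(x, depth, max_depth) {
  n <- nrow(x)
  if (n <= 1 || depth >= max_depth) return(list(size = n))
  rng <- apply(x, 2, range)
  usable <- which(rng[2, ] > rng[1, ])
  if (!length(usable)) return(list(size = n))
  q <- if (length(usable) == 1) usable else sample(usable, 1)
  p <- runif(1, rng[1, q], rng[2, q])
  left <- x[, q] < p
  list(q = q, p = p,
       left = iforest_tree(x[left, , drop = FALSE], depth + 1, max_depth),
       right = iforest_tree(x[!left, , drop = FALSE], depth + 1, max_depth))
}

iforest_path <- function(tree, x, depth = 0) {
  if (is.null(tree$q)) return(depth + iforest_cn(tree$size))
  if (x[tree$q] < tree$p) iforest_path(tree$left, x, depth + 1)
  else iforest_path(tree$right, x, depth + 1)
}

#' Isolation-forest anomaly scores
#'
#' Standard isolation forest: trees grown on random subsamples with random
#' axis-aligned splits; anomaly score `2^(-E[h]/c(psi))` from the average
#' path length over trees.  Scores near 1 indicate easily isolated
#' (anomalous) points.
#'
#' @param x numeric matrix (rows = observations).
#' @param ntrees number of isolation trees.
#' @param sample_size subsample size per tree (capped at `nrow(x)`).
#' @param seed integer.
#' @return numeric vector of anomaly scores in (0, 1).
#' @export
isolation_forest_scores <- function(x, ntrees = 100, sample_size = 256,
                                    seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  psi <- min(sample_size, n)
  max_depth <- ceiling(log2(max(psi, 2)))
  with_rng_seed(seed, {
    trees <- lapply(seq_len(ntrees), function(i) {
      idx <- sample.int(n, psi)
      iforest_tree(x[idx, , drop = FALSE], 0, max_depth)
    })
    paths <- vapply(seq_len(n), function(i) {
      mean(vapply(trees, iforest_path, numeric(1), x = x[i, ]))
    }, numeric(1))
    2^(-paths / iforest_cn(psi))
  })
}

#' Flag outlying subjects on the core medical features
#'
#' Fits an isolation forest on exactly the four features used for cohort
#' cleaning -- insulin sensitivity, BMI, HbA1c and the total adipose tissue
#' estimate -- and drops rows whose anomaly score falls above the
#' `1 - contamination` quantile.
#'
#' @param features data.frame with columns `insulin_sensitivity`, `bmi`,
#'   `hba1c`, `total_adipose_volume`.
#' @param contamination fraction of rows to drop (0 keeps everything).
#' @param ntrees,sample_size,seed forwarded to the forest.
#' @return logical keep-mask (TRUE = retain), with scores as an attribute.
#' @export
remove_outliers <- function(features, contamination = 0.05, ntrees = 100,
                            sample_size = 256, seed = 1L) {
  needed <- c("insulin_sensitivity", "bmi", "hba1c", "total_adipose_volume")
  if (!all(needed %in% names(features)))
    stop("missing feature column(s): ",
         paste(setdiff(needed, names(features)), collapse = ", "))
  if (contamination < 0 || contamination >= 1)
    stop("contamination must be in [0, 1)")
  x <- as.matrix(features[needed])
  if (anyNA(x)) stop("features must be complete for outlier removal")
  if (contamination == 0)
    return(structure(rep(TRUE, nrow(x)), scores = rep(NA_real_, nrow(x))))
  scores <- isolation_forest_scores(x, ntrees, sample_size, seed)
  # drop the top `contamination` fraction by score; ties broken by index so
  # no more than ceiling(contamination * n) rows are ever removed
  n_drop <- floor(contamination * nrow(x))
  keep <- rep(TRUE, nrow(x))
  if (n_drop > 0)
    keep[order(scores, decreasing = TRUE)[seq_len(n_drop)]] <- FALSE
  structure(keep, scores = scores)
}

#' Min-max normalize continuous labels using training-fold extrema
#'
#' Scales each continuous label to \[0,1\] with extrema computed on the
#' training rows only, keeps a per-label missingness mask (missing labels are
#' masked from that label's loss rather than discarding the scan), and
#' retains the inverse transform so normalized errors can be reported on the
#' original scale (`absolute MAE = normalized MAE * training range`).
#'
#' @param labels data.frame.
#' @param cols character vector of continuous label columns.
#' @param train_idx row indices defining the training fold (default: all).
#' @return list with `labels` (normalized), `mask` (logical matrix),
#'   `transforms` (per-label c(min, max)) and helper closure `denormalize`.
#' @export
normalize_labels <- function(labels, cols, train_idx = seq_len(nrow(labels))) {
  transforms <- list()
  mask <- matrix(TRUE, nrow(labels), length(cols),
                 dimnames = list(NULL, cols))
  out <- labels
  for (cl in cols) {
    v <- labels[[cl]]
    rng <- range(v[train_idx], na.rm = TRUE)
    if (!all(is.finite(rng)) || diff(rng) == 0)
      stop("constant or empty label column: ", cl)
    out[[cl]] <- (v - rng[1]) / diff(rng)
    mask[, cl] <- !is.na(v)
    transforms[[cl]] <- c(min = rng[1], max = rng[2])
  }
  list(labels = out, mask = mask, transforms = transforms,
       denormalize = function(value, col) {
         tr <- transforms[[col]]
         value * (tr["max"] - tr["min"]) + tr["min"]
       })
}

# Largest-remainder apportionment of n into parts proportional to frac.
largest_remainder <- function(n, frac) {
  q <- n * frac
  f <- floor(q)
  rem <- n - sum(f)
  if (rem > 0) {
    add <- order(q - f, decreasing = TRUE)[seq_len(rem)]
    f[add] <- f[add] + 1
  }
  as.integer(f)
}

#' Stratified train/validation/test split
#'
#' Strata are formed by binning BMI and insulin sensitivity into
#' `n_bins`-tiles crossed with diabetes status; singleton strata are merged
#' into the nearest stratum (same diabetes status, closest bins).  Within
#' each stratum, subjects are randomly assigned to folds so that per-stratum
#' allocations are within one subject of the target fractions and the global
#' fold sizes are exact up to integer rounding.
#'
#' @param labels data.frame with the strata variables.
#' @param fractions train/validation/test fractions summing to 1.
#' @param strata_vars columns used for stratification; the first two are
#'   binned continuous variables, the third is a binary status.
#' @param n_bins quantile bins for the continuous variables.
#' @param seed integer.
#' @return data.frame with `id`, `fold` (train/validation/test), `stratum`.
#' @export
stratified_split <- function(labels,
                             fractions = c(train = 0.70, validation = 0.15,
                                           test = 0.15),
                             strata_vars = c("bmi", "insulin_sensitivity",
                                             "Da"),
                             n_bins = 3, seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  n <- nrow(labels)
  bin_of <- function(v) {
    qs <- unique(quantile(v, probs = seq(0, 1, length.out = n_bins + 1),
                          na.rm = TRUE))
    if (length(qs) < 2) return(rep(1L, length(v)))
    as.integer(cut(v, qs, include.lowest = TRUE))
  }
  b1 <- bin_of(labels[[strata_vars[1]]])
  b2 <- bin_of(labels[[strata_vars[2]]])
  b3 <- as.integer(labels[[strata_vars[3]]])
  key <- interaction(b1, b2, b3, drop = TRUE)
  stratum <- as.integer(key)
  # merge singleton strata into the nearest stratum (same status, then bins)
  repeat {
    sizes <- table(stratum)
    singles <- as.integer(names(sizes)[sizes == 1])
    if (!length(singles) || length(sizes) == 1) break
    s <- singles[1]
    i <- which(stratum == s)
    cand <- setdiff(unique(stratum), s)
    dist <- vapply(cand, function(cs) {
      j <- which(stratum == cs)[1]
      (b1[i] - b1[j])^2 + (b2[i] - b2[j])^2 + 10 * (b3[i] - b3[j])^2
    }, numeric(1))
    stratum[i] <- cand[which.min(dist)]
  }
  strata <- sort(unique(stratum))
  if (n < 2 * length(strata)) stop("need at least 2 subjects per stratum")
  ns <- as.integer(table(factor(stratum, levels = strata)))
  S <- length(strata); K <- length(fractions)
  targets <- largest_remainder(n, fractions)
  alloc <- t(vapply(ns, function(m) floor(m * fractions), numeric(K)))
  alloc <- matrix(as.integer(alloc), S, K)
  rem_s <- ns - rowSums(alloc)
  need_f <- targets - colSums(alloc)
  fracpart <- t(vapply(seq_len(S), function(s) ns[s] * fractions -
                                     floor(ns[s] * fractions), numeric(K)))
  ord <- order(as.vector(fracpart), decreasing = TRUE)
  for (idx in ord) {
    s <- (idx - 1) %% S + 1
    f <- (idx - 1) %/% S + 1
    if (rem_s[s] > 0 && need_f[f] > 0) {
      alloc[s, f] <- alloc[s, f] + 1L
      rem_s[s] <- rem_s[s] - 1L
      need_f[f] <- need_f[f] - 1L
    }
  }
  # repair any leftover (rare; keeps totals exact)
  while (any(rem_s > 0)) {
    s <- which(rem_s > 0)[1]
    f <- which(need_f > 0)[1]
    alloc[s, f] <- alloc[s, f] + 1L
    rem_s[s] <- rem_s[s] - 1L
    need_f[f] <- need_f[f] - 1L
  }
  fold_names <- names(fractions) %||% c("train", "validation", "test")
  fold <- character(n)
  with_rng_seed(seed, {
    for (si in seq_len(S)) {
      members <- sample(which(stratum == strata[si]))
      fold[members] <- rep(fold_names, times = alloc[si, ])
    }
  })
  data.frame(id = labels$id %||% seq_len(n), fold = fold, stratum = stratum)
}
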