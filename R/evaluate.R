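#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC with midrank tie handling: the
#' probability that a random positive is scored above a random negative,
#' counting ties as 1/2.  Equivalent to the trapezoidal area over all
#' thresholds.
#'
#' @param scores numeric scores, larger = more positive.
#' @param labels 0/1 truth.
#' @return AUROC in \[0,1\]; `NA` with a warning when only one class is
#'   present (undefined).
#' @export
auroc <- function(scores, labels) {
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- as.integer(labels[ok])
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    warning("AUROC undefined: single-class truth")
    return(NA_real_)
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Fat-compartment volumes of a phantom
#'
#' Total, visceral (upper + lower) and upper-extremity adipose tissue
#' volumes, computed as fat-voxel counts within the relevant ground-truth
#' masks times the voxel volume.  Fat voxels are those at or above the
#' bright-fat intensity cutoff on the raw phantom scale.
#'
#' @param volume a `body_volume` with `region_masks` and `spacing`.
#' @param fat_threshold raw-intensity cutoff for fat.
#' @return list with `total_adipose_volume`, `visceral_adipose_volume`,
#'   `upper_extremity_adipose_volume` (litres).
#' @export
compartment_volumes <- function(volume, fat_threshold = 0.75) {
  if (is.null(volume$region_masks) || is.null(volume$body_mask))
    stop("compartment volumes need ground-truth masks")
  fat <- volume$voxels >= fat_threshold
  vox_l <- prod(volume$spacing) / 1e6   # mm^3 -> litres
  list(
    total_adipose_volume = sum(fat & volume$body_mask) * vox_l,
    visceral_adipose_volume =
      sum(fat & (volume$region_masks$visceral_upper |
                   volume$region_masks$visceral_lower)) * vox_l,
    upper_extremity_adipose_volume =
      sum(fat & volume$region_masks$arm) * vox_l)
}

#' Classification/regression metric table
#'
#' AUROC per binary label and normalized MAE per regression label, with
#' de-normalized absolute MAE when inverse transforms are supplied.  For
#' scarce-positive binary labels the evaluation rows can be the pooled
#' validation + test folds.
#'
#' @param predictions data.frame with `prob_<label>` / `pred_<label>`
#'   columns (as produced by [infer()]).
#' @param truth data.frame with one column per label (regression columns on
#'   the normalized scale).
#' @param class_labels,reg_labels label names to score.
#' @param transforms optional [normalize_labels()] `transforms` for
#'   absolute-scale MAE.
#' @return data.frame with label, metric, value (and `absolute` for MAE).
#' @export
score_metrics <- function(predictions, truth,
                          class_labels = c("sex", "Da", "Db", "Dg"),
                          reg_labels = c("age", "bmi",
                                         "insulin_sensitivity", "hba1c"),
                          transforms = NULL) {
  rows <- list()
  for (h in intersect(class_labels, names(truth))) {
    sc <- predictions[[paste0("prob_", h)]]
    if (is.null(sc)) next
    val <- if (length(unique(stats::na.omit(truth[[h]]))) == 2)
      auroc(sc, truth[[h]]) else NA_real_
    rows[[length(rows) + 1L]] <-
      data.frame(label = h, metric = "auroc", value = val,
                 absolute = NA_real_)
  }
  for (h in intersect(reg_labels, names(truth))) {
    pr <- predictions[[paste0("pred_", h)]]
    if (is.null(pr)) next
    ok <- !is.na(truth[[h]])
    m <- mean(abs(pr[ok] - truth[[h]][ok]))
    absm <- if (!is.null(transforms) && !is.null(transforms[[h]]))
      m * unname(diff(transforms[[h]])) else NA_real_
    rows[[length(rows) + 1L]] <-
      data.frame(label = h, metric = "mae", value = m, absolute = absm)
  }
  if (!length(rows))
    return(data.frame(label = character(0), metric = character(0),
                      value = numeric(0), absolute = numeric(0)))
  do.call(rbind, rows)
}

# mean of the k nearest training responses (Euclidean on scaled features)
knn_regress <- function(xtrain, ytrain, xtest, k = 5) {
  k <- min(k, nrow(xtrain))
  apply(xtest, 1, function(q) {
    d <- sqrt(colSums((t(xtrain) - q)^2))
    mean(ytrain[order(d)[seq_len(k)]])
  })
}

#' Fat-compartment benchmark models
#'
#' The conventional comparison models: linear regression, k-nearest
#' neighbours, random forest and support vector machine, fit on the three
#' segmented fat-compartment volumes (total, visceral, upper-extremity) and
#' scored with the same metrics as the network.
#'
#' @param features data.frame with the three compartment columns.
#' @param labels data.frame with the target columns (regression targets
#'   normalized).
#' @param folds data.frame from [stratified_split()].
#' @param class_labels,reg_labels targets to fit.
#' @param eval_folds folds pooled for evaluation (default validation+test,
#'   the scarce-positive handling).
#' @param knn_k,rf_trees benchmark hyperparameters.
#' @param seed integer.
#' @return data.frame with model, label, metric, value.
#' @export
fit_benchmarks <- function(features, labels, folds,
                           class_labels = c("Da"),
                           reg_labels = character(0),
                           eval_folds = c("validation", "test"),
                           knn_k = 5, rf_trees = 200, seed = 1L) {
  fcols <- c("total_adipose_volume", "visceral_adipose_volume",
             "upper_extremity_adipose_volume")
  if (!all(fcols %in% names(features)))
    stop("features must contain: ", paste(fcols, collapse = ", "))
  x <- as.matrix(features[fcols])
  if (any(apply(x, 2, sd) == 0))
    warning("degenerate (zero-variance) compartment feature")
  tr <- folds$fold == "train"
  ev <- folds$fold %in% eval_folds
  mu <- colMeans(x[tr, , drop = FALSE])
  sg <- pmax(apply(x[tr, , drop = FALSE], 2, sd), 1e-12)
  xs <- sweep(sweep(x, 2, mu), 2, sg, `/`)
  rows <- list()
  add <- function(model, label, metric, value)
    rows[[length(rows) + 1L]] <<-
      data.frame(model = model, label = label, metric = metric,
                 value = value)
  with_rng_seed(seed, {
    for (h in class_labels) {
      y <- labels[[h]]
      ok_tr <- tr & !is.na(y)
      ok_ev <- ev & !is.na(y)
      if (length(unique(y[ok_tr])) < 2 || length(unique(y[ok_ev])) < 2) next
      dtr <- data.frame(y = y[ok_tr], xs[ok_tr, , drop = FALSE])
      dev <- data.frame(xs[ok_ev, , drop = FALSE])
      # linear regression on the 0/1 label, scored by the fitted value
      sc_lin <- predict(lm(y ~ ., data = dtr), dev)
      add("linear", h, "auroc", auroc(sc_lin, y[ok_ev]))
      kn <- class::knn(xs[ok_tr, , drop = FALSE], xs[ok_ev, , drop = FALSE],
                       factor(y[ok_tr]), k = knn_k, prob = TRUE)
      pwin <- attr(kn, "prob")
      sc_knn <- ifelse(kn == "1", pwin, 1 - pwin)
      add("knn", h, "auroc", auroc(sc_knn, y[ok_ev]))
      rf <- randomForest::randomForest(x = xs[ok_tr, , drop = FALSE],
                                       y = factor(y[ok_tr]),
                                       ntree = rf_trees)
      sc_rf <- predict(rf, xs[ok_ev, , drop = FALSE],
                       type = "prob")[, "1"]
      add("random_forest", h, "auroc", auroc(sc_rf, y[ok_ev]))
      sv <- e1071::svm(x = xs[ok_tr, , drop = FALSE], y = factor(y[ok_tr]),
                       probability = TRUE)
      sc_sv <- attr(predict(sv, xs[ok_ev, , drop = FALSE],
                            probability = TRUE),
                    "probabilities")[, "1"]
      add("svm", h, "auroc", auroc(sc_sv, y[ok_ev]))
    }
    for (h in reg_labels) {
      y <- labels[[h]]
      ok_tr <- tr & !is.na(y)
      ok_ev <- ev & !is.na(y)
      if (!any(ok_tr) || !any(ok_ev)) next
      dtr <- data.frame(y = y[ok_tr], xs[ok_tr, , drop = FALSE])
      dev <- data.frame(xs[ok_ev, , drop = FALSE])
      mae_of <- function(p) mean(abs(p - y[ok_ev]))
      add("linear", h, "mae", mae_of(predict(lm(y ~ ., data = dtr), dev)))
      add("knn", h, "mae",
          mae_of(knn_regress(xs[ok_tr, , drop = FALSE], y[ok_tr],
                             xs[ok_ev, , drop = FALSE], knn_k)))
      rf <- randomForest::randomForest(x = xs[ok_tr, , drop = FALSE],
                                       y = y[ok_tr], ntree = rf_trees)
      add("random_forest", h, "mae",
          mae_of(predict(rf, xs[ok_ev, , drop = FALSE])))
      sv <- e1071::svm(x = xs[ok_tr, , drop = FALSE], y = y[ok_tr])
      add("svm", h, "mae", mae_of(predict(sv, xs[ok_ev, , drop = FALSE])))
    }
  })
  if (!length(rows))
    return(data.frame(model = character(0), label = character(0),
                      metric = character(0), value = numeric(0)))
  do.call(rbind, rows)
}
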