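#' Write / read body volumes as NIfTI
#'
#' Volumes are stored as double-precision NIfTI (`.nii.gz`) with voxel
#' spacing in the header and axis order in a JSON sidecar; the body mask and
#' region masks go to a companion integer label map (`<path>_regions`),
#' giving a lossless round trip of voxels, masks and axis metadata.
#'
#' @param volume a `body_volume`.
#' @param path output path (`.nii.gz`).
#' @return `write_volume` returns `path` invisibly; `read_volume` returns
#'   the reconstructed `body_volume`.
#' @export
write_volume <- function(volume, path) {
  RNifti::writeNifti(RNifti::asNifti(volume$voxels,
                                     pixdim = volume$spacing,
                                     datatype = "double"), path)
  base <- sub("\\.nii(\\.gz)?$", "", path)
  lab <- array(0L, dim(volume$voxels))
  lab[volume$body_mask] <- length(adiponet_regions) + 1L
  if (!is.null(volume$region_masks))
    for (i in seq_along(adiponet_regions))
      lab[volume$region_masks[[adiponet_regions[i]]]] <- i
  RNifti::writeNifti(RNifti::asNifti(lab, pixdim = volume$spacing,
                                     datatype = "int16"),
                     paste0(base, "_regions.nii.gz"))
  jsonlite::write_json(list(axis_order = volume$axis_order,
                            spacing = volume$spacing,
                            profile = volume$profile %||% NA,
                            region_codes = adiponet_regions),
                       paste0(base, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such volume file: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("malformed volume file '", path,
                                           "': ", conditionMessage(e)))
  base <- sub("\\.nii(\\.gz)?$", "", path)
  meta <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  lab <- array(0L, dim(img))
  regfile <- paste0(base, "_regions.nii.gz")
  region_masks <- NULL
  body <- NULL
  if (file.exists(regfile)) {
    lab <- as.array(RNifti::readNifti(regfile))
    body <- lab > 0L
    region_masks <- lapply(seq_along(adiponet_regions), function(i)
      array(lab == i, dim(img)))
    names(region_masks) <- adiponet_regions
  }
  structure(list(voxels = as.array(img), body_mask = body,
                 region_masks = region_masks,
                 spacing = as.numeric(meta$spacing),
                 axis_order = meta$axis_order,
                 profile = meta$profile),
            class = "body_volume")
}

preprocess_cohort <- function(cohort, config, stats = NULL) {
  grid <- config$grid
  pp <- config$preprocess
  shaped <- lapply(cohort$volumes, normalize_shape,
                   profile = grid, antialias = isTRUE(pp$antialias))
  if (is.null(stats) && identical(pp$voxel_stats, "global"))
    stats <- compute_body_stats(lapply(shaped, `[[`, "voxels"))
  out <- lapply(shaped, function(v)
    center_volume(normalize_voxels(v, stats = stats,
                                   trunc_sd = pp$trunc_sd,
                                   shift_eps = pp$shift_eps)))
  list(volumes = out, stats = stats)
}

#' Run the full pipeline end to end
#'
#' Executes simulate -> preprocess -> split -> train -> select -> infer ->
#' saliency -> cluster -> evaluate on a synthetic cohort, writing every
#' stage's outputs and a manifest (config hash, seeds, package version)
#' under `out_dir`.  The tiny profile completes on one CPU in minutes.
#'
#' @param config from [default_config()].
#' @param out_dir run directory (created).
#' @param seed master seed; every stochastic stage derives its seed from it.
#' @param n cohort size (default from the profile's pipeline block).
#' @param max_epochs training epochs (default from the profile).
#' @param write_volumes also write every preprocessed volume as NIfTI.
#' @param verbose print stage progress.
#' @return list with the run artifacts (invisibly also written to disk).
#' @export
run_pipeline <- function(config = default_config("tiny"), out_dir,
                         seed = 1L, n = NULL, max_epochs = NULL,
                         write_volumes = FALSE, verbose = TRUE) {
  t0 <- Sys.time()
  prof <- config$profile
  n <- n %||% config$pipeline[[prof]]$n
  max_epochs <- max_epochs %||% config$pipeline[[prof]]$max_epochs
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message("[", ep_time(t0), "] ", ...)
  stage <- function(name, expr) {
    say("stage: ", name)
    tryCatch(expr, error = function(e)
      stop("pipeline failed in stage '", name, "': ",
           conditionMessage(e), call. = FALSE))
  }

  cohort <- stage("simulate",
                  generate_cohort(n, config$label_model, seed = seed,
                                  profile = config$grid))
  write.csv(cohort$labels, file.path(out_dir, "labels.csv"),
            row.names = FALSE)
  write.csv(cohort$followup, file.path(out_dir, "followup.csv"),
            row.names = FALSE)

  feats <- stage("compartments", {
    cv <- lapply(cohort$volumes, compartment_volumes,
                 fat_threshold = config$evaluate$fat_threshold)
    do.call(rbind, lapply(cv, as.data.frame))
  })
  write.csv(feats, file.path(out_dir, "compartments.csv"), row.names = FALSE)

  keep <- stage("outliers", {
    ft <- data.frame(insulin_sensitivity = cohort$labels$insulin_sensitivity,
                     bmi = cohort$labels$bmi, hba1c = cohort$labels$hba1c,
                     total_adipose_volume = feats$total_adipose_volume)
    remove_outliers(ft, contamination = config$preprocess$outlier_contamination,
                    seed = seed + 1L)
  })
  labels <- cohort$labels[keep, ]
  followup <- cohort$followup[keep, ]
  volumes <- cohort$volumes[keep]
  feats <- feats[keep, ]

  folds <- stage("split",
                 stratified_split(labels,
                                  setNames(config$preprocess$split_fractions,
                                           c("train", "validation", "test")),
                                  n_bins = config$preprocess$strata_bins,
                                  seed = seed + 2L))
  write.csv(folds, file.path(out_dir, "folds.csv"), row.names = FALSE)

  norm <- stage("normalize_labels", {
    tr_idx <- which(folds$fold == "train")
    normalize_labels(labels, c("age", "bmi", "insulin_sensitivity", "hba1c"),
                     train_idx = tr_idx)
  })
  jsonlite::write_json(norm$transforms,
                       file.path(out_dir, "label_transforms.json"),
                       auto_unbox = TRUE, digits = NA)

  prep <- stage("preprocess", preprocess_cohort(
    list(volumes = volumes), config))
  jsonlite::write_json(prep$stats %||% list(per_scan = TRUE),
                       file.path(out_dir, "voxel_norm.json"),
                       auto_unbox = TRUE, digits = NA)
  if (write_volumes) {
    vd <- file.path(out_dir, "volumes")
    dir.create(vd, showWarnings = FALSE)
    for (i in seq_along(prep$volumes))
      write_volume(prep$volumes[[i]],
                   file.path(vd, sprintf("scan%04d.nii.gz", labels$id[i])))
  }

  training <- stage("train", {
    net <- build_model(model_config(max_epochs = max_epochs),
                       config$grid$final_dims, seed = seed + 3L)
    aug <- augment_config(max_pad = config$augment$max_pad,
                          rotate = config$augment$rotate,
                          rot_vertical = config$augment$rot_vertical,
                          rot_other = config$augment$rot_other,
                          noise = config$augment$noise,
                          noise_sd = config$augment$noise_sd,
                          zoom = config$augment$zoom,
                          zoom_range = config$augment$zoom_range)
    train_model(net, prep$volumes, norm$labels, folds, seed = seed + 4L,
                augment = aug, max_epochs = max_epochs, verbose = verbose)
  })
  write.csv(training$history, file.path(out_dir, "history.csv"),
            row.names = FALSE)

  best <- stage("select", select_checkpoint(training))
  load_checkpoint(training$net, best)

  inf <- stage("infer", infer(training$net, prep$volumes))
  write.csv(cbind(id = labels$id, inf$predictions),
            file.path(out_dir, "predictions.csv"), row.names = FALSE)

  sal <- stage("saliency", {
    pos <- which(labels$Da == 1)
    if (!length(pos)) pos <- seq_len(min(10, nrow(labels)))
    maps <- lapply(pos, function(i)
      gradient_x_input(training$net, prep$volumes[[i]], "Da",
                       true_label = labels$Da[i]))
    rf <- region_fractions(maps, prep$volumes[[pos[1]]]$region_masks,
                           top_share = config$saliency$top_share,
                           region_share = config$saliency$region_share)
    list(maps = maps, report = rf)
  })
  write.csv(sal$report, file.path(out_dir, "region_report.csv"),
            row.names = FALSE)

  clus <- stage("cluster", {
    d <- gower_matrix(inf$embeddings)
    res <- pam_silhouette(d, config$cluster$k_min:config$cluster$k_max)
    stab <- bootstrap_stability(d, res, B = config$cluster$bootstrap_B,
                                seed = seed + 5L)
    oc <- tryCatch(
      outcome_analysis(res$assignments, followup,
                       labels[c("sex", "age", "bmi", "hba1c")]),
      error = function(e) NULL)
    list(result = res, stability = stab, outcomes = oc)
  })
  write.csv(data.frame(id = labels$id, cluster = clus$result$assignments),
            file.path(out_dir, "clusters.csv"), row.names = FALSE)
  write.csv(clus$result$silhouette, file.path(out_dir, "silhouette.csv"),
            row.names = FALSE)

  eval_tab <- stage("evaluate", {
    net_metrics <- score_metrics(
      inf$predictions[folds$fold %in% c("validation", "test"), ],
      norm$labels[folds$fold %in% c("validation", "test"), ],
      transforms = norm$transforms)
    bench <- fit_benchmarks(feats, norm$labels, folds,
                            class_labels = c("Da"),
                            reg_labels = c("bmi"),
                            knn_k = config$evaluate$knn_k,
                            rf_trees = config$evaluate$rf_trees,
                            seed = seed + 6L)
    list(network = net_metrics, benchmarks = bench)
  })
  write.csv(eval_tab$network, file.path(out_dir, "network_metrics.csv"),
            row.names = FALSE)
  write.csv(eval_tab$benchmarks, file.path(out_dir, "benchmark_metrics.csv"),
            row.names = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("adiponet")),
    seed = seed, n = n, profile = prof, max_epochs = max_epochs,
    config_hash = config_hash(config),
    selected_epoch = best$epoch,
    k_selected = clus$result$k)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  say("done")
  invisible(list(cohort = cohort, labels = labels, folds = folds,
                 training = training, best = best, inference = inf,
                 saliency = sal, clustering = clus, evaluation = eval_tab,
                 manifest = manifest, out_dir = out_dir))
}

ep_time <- function(t0) sprintf("%.1fs", as.numeric(Sys.time() - t0,
                                                    units = "secs"))

# deterministic hash of the configuration (md5 of its canonical serialization)
config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tf)
  unname(tools::md5sum(tf))
}
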