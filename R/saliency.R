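#' Gradients-times-input attribution map
#'
#' Computes the per-voxel product of the input intensity and the gradient of
#' a selected output node with respect to that voxel, on the frozen network
#' in evaluation mode.  For classification heads only the output node
#' matching the true label is differentiated (e.g., for a female-labelled
#' scan, only the gradient that increases the female probability); for
#' regression heads the single output is differentiated and only positive
#' gradient components are kept.  Wherever the input is zero the map is
#' exactly zero.
#'
#' @param net trained `adiponet_net` (evaluation mode is enforced here).
#' @param volume preprocessed, centred volume (array or `body_volume`).
#' @param head output head name.
#' @param true_label 0/1 true label; required for classification heads.
#' @param positive_only for classification: drop negative gradient
#'   components before the product (default keeps them).
#' @return A `gradient_map`: `values` (array aligned with the input),
#'   `target`, `mode`.
#' @export
gradient_x_input <- function(net, volume, head, true_label = NULL,
                             positive_only = FALSE) {
  if (!head %in% names(net$heads)) stop("unknown head: ", head)
  x <- if (is.list(volume)) volume$voxels else volume
  fw <- nn_forward(net, x, training = FALSE, keep_cache = TRUE)
  hd <- net$heads[[head]]
  if (hd$kind == "class") {
    if (is.null(true_label)) stop("true_label required for classification heads")
    node <- as.integer(true_label) + 1L
    # gradient of the selected probability node through the softmax
    p <- fw$class_probs[[head]]
    dz <- -p * p[, node]
    dz[, node] <- dz[, node] + p[, node]
  } else {
    dz <- matrix(1, 1, 1)
  }
  dE <- dz %*% t(net$par[[hd$W]])
  bw <- nn_backward(net, fw, dE, need_dx = TRUE)
  g <- bw$dx
  dim(g) <- dim(x)
  if (hd$kind == "reg" || positive_only) g <- pmax(g, 0)
  structure(list(values = g * x, target = head,
                 mode = if (hd$kind == "reg" || positive_only)
                   "positive_gradients" else "signed",
                 true_label = true_label),
            class = "gradient_map")
}

#' Postprocess a gradient map for display and scoring
#'
#' Gaussian smoothing, contrast clipping of extreme attribution magnitudes
#' at a quantile, and averaging along the coronal axis for a 2D projection.
#' The enhanced 3D map is retained for region scoring.
#'
#' @param map a `gradient_map`.
#' @param sigma Gaussian smoothing SD in voxels.
#' @param clip_quantile absolute-value quantile at which values are clipped.
#' @return list with `projection` (2D: vertical x sagittal) and `enhanced`
#'   (3D array).
#' @export
postprocess_heatmap <- function(map, sigma = 2, clip_quantile = 0.99) {
  v <- map$values
  sm <- blur_volume(v, sigma)
  lim <- quantile(abs(sm), clip_quantile)
  if (lim > 0) sm <- pmin(pmax(sm, -lim), lim)
  list(projection = apply(sm, c(1, 2), mean), enhanced = sm)
}

#' Automated anatomical region scoring of gradient maps
#'
#' Mechanized analogue of expert heatmap rating: a map "highlights" a region
#' when the region contains at least `region_share` of the map's top
#' `top_share` attribution voxels (by absolute value, among voxels with
#' nonzero attribution).  Reported per region as the fraction of maps that
#' highlight it.
#'
#' @param maps list of `gradient_map`s (or bare arrays).
#' @param region_masks named list of logical arrays aligned to the maps.
#' @param top_share fraction of attribution voxels considered highlighted.
#' @param region_share minimum share of the top voxels inside a region.
#' @return data.frame with `region`, `fraction` (of maps highlighting it)
#'   and `mean_share` (average share of top voxels inside the region).
#' @export
region_fractions <- function(maps, region_masks, top_share = 0.05,
                             region_share = 0.10) {
  if (inherits(maps, "gradient_map") || is.array(maps)) maps <- list(maps)
  regions <- names(region_masks)
  hits <- matrix(0, length(maps), length(regions),
                 dimnames = list(NULL, regions))
  shares <- hits
  for (i in seq_along(maps)) {
    a <- abs(if (is.list(maps[[i]])) maps[[i]]$values else maps[[i]])
    if (!all(dim(a) == dim(region_masks[[1]])))
      stop("region masks are not aligned to the gradient maps")
    nz <- which(a > 0)
    if (!length(nz)) next
    ntop <- max(1L, ceiling(top_share * length(nz)))
    top <- nz[order(a[nz], decreasing = TRUE)[seq_len(ntop)]]
    for (r in regions) {
      sh <- sum(region_masks[[r]][top]) / ntop
      shares[i, r] <- sh
      hits[i, r] <- as.numeric(sh >= region_share)
    }
  }
  data.frame(region = regions, fraction = colMeans(hits),
             mean_share = colMeans(shares), row.names = NULL)
}
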