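#' Augmentation configuration
#'
#' @param max_pad maximum random zero-padding per side, voxels.
#' @param rotate,noise,zoom enable flags per transform.
#' @param rot_vertical,rot_other rotation half-ranges in degrees about the
#'   vertical and the two horizontal axes.
#' @param noise_sd Gaussian noise SD added to body voxels (background stays
#'   exactly 0).
#' @param zoom_range zoom half-range as a fraction (must lie in (0, 1)).
#' @return An `augment_config` list.
#' @export
augment_config <- function(max_pad = 2, rotate = TRUE, rot_vertical = 10,
                           rot_other = 5, noise = TRUE, noise_sd = 0.05,
                           zoom = FALSE, zoom_range = 0.10) {
  if (max_pad < 0 || rot_vertical < 0 || rot_other < 0 || noise_sd < 0)
    stop("augmentation ranges must be nonnegative")
  if (zoom_range <= 0 || zoom_range >= 1)
    stop("zoom_range must lie in (0, 1)")
  structure(list(max_pad = max_pad, rotate = rotate,
                 rot_vertical = rot_vertical, rot_other = rot_other,
                 noise = noise, noise_sd = noise_sd, zoom = zoom,
                 zoom_range = zoom_range), class = "augment_config")
}

#' Training-time volume augmentation
#'
#' Applies, in order: random zero-padding per side (realized as an integer
#' translation once the padded grid is cropped back to the input
#' dimensions), random small-angle rotations about each axis, Gaussian noise
#' added to body voxels only, and optional random zoom.  The output always
#' has the input grid dimensions.  A degenerate configuration (everything
#' disabled or zero) is the identity.  Draws come from the current RNG
#' stream, so a seeded caller gets reproducible augmentation.
#'
#' @param volume `body_volume` or bare 3D array.
#' @param cfg an [augment_config()].
#' @return Augmented array (bare) or volume with augmented `voxels`.
#' @export
augment_volume <- function(volume, cfg = augment_config()) {
  bare <- !is.list(volume)
  x <- if (bare) volume else volume$voxels
  if (cfg$max_pad > 0) {
    pads <- sample.int(cfg$max_pad + 1L, 6, replace = TRUE) - 1L
    shift <- c(pads[1] - floor((pads[1] + pads[2]) / 2),
               pads[3] - floor((pads[3] + pads[4]) / 2),
               pads[5] - floor((pads[5] + pads[6]) / 2))
    if (any(shift != 0)) x <- shift_volume(x, shift)
  }
  if (isTRUE(cfg$rotate)) {
    angs <- c(runif(1, -cfg$rot_vertical, cfg$rot_vertical),
              runif(1, -cfg$rot_other, cfg$rot_other),
              runif(1, -cfg$rot_other, cfg$rot_other))
    for (ax in 1:3) if (angs[ax] != 0) x <- rotate_volume(x, ax, angs[ax])
  }
  if (isTRUE(cfg$noise) && cfg$noise_sd > 0) {
    body <- x > 0
    nb <- sum(body)
    if (nb > 0)
      x[body] <- pmax(x[body] + rnorm(nb, sd = cfg$noise_sd), 1e-6)
  }
  if (isTRUE(cfg$zoom)) {
    f <- 1 + runif(1, -cfg$zoom_range, cfg$zoom_range)
    d <- dim(x)
    inner <- pmax(round(d / f), 2)
    x <- resize_volume(resize_volume(x, inner), d)
  }
  if (bare) return(x)
  volume$voxels <- x
  volume
}

#' Center a body volume on its grid
#'
#' Moves the body-mask centroid to the grid centre by an integer zero-fill
#' shift; no stochastic transform is applied.  This is the (deterministic)
#' validation/test counterpart of [augment_volume()].  Idempotent up to the
#' half-voxel rounding of the centroid.
#'
#' @param volume `body_volume` or bare 3D array (body = voxels > 0).
#' @return The centered volume; masks are shifted identically.
#' @export
center_volume <- function(volume) {
  bare <- !is.list(volume)
  x <- if (bare) volume else volume$voxels
  body <- if (!bare && !is.null(volume$body_mask)) volume$body_mask else x > 0
  if (!any(body)) return(volume)
  d <- dim(x)
  idx <- which(body, arr.ind = TRUE)
  centroid <- colMeans(idx)
  shift <- round((d + 1) / 2 - centroid)
  if (all(shift == 0)) return(volume)
  x <- shift_volume(x, shift)
  if (bare) return(x)
  volume$voxels <- x
  volume$body_mask <- shift_volume(body, shift, fill = FALSE) > 0
  if (!is.null(volume$region_masks))
    volume$region_masks <- lapply(volume$region_masks, function(m)
      shift_volume(m, shift, fill = FALSE) > 0)
  volume
}

#' Crop a volume to the torso or abdominal window
#'
#' Zeroes all voxels (and mask entries) outside a configured vertical-axis
#' window, keeping the grid dimensions -- the restricted-field-of-view input
#' used in sensitivity analyses.  Windows are fractions of the vertical grid
#' axis, which makes repeated cropping idempotent.
#'
#' @param volume `body_volume` or bare 3D array.
#' @param region `"torso"` or `"abdomen"`.
#' @param windows named list of `c(lo, hi)` vertical fractions.
#' @return The cropped volume.
#' @export
crop_region <- function(volume, region = c("torso", "abdomen"),
                        windows = list(torso = c(0.12, 0.56),
                                       abdomen = c(0.36, 0.56))) {
  region <- match.arg(region, names(windows))
  w <- windows[[region]]
  bare <- !is.list(volume)
  x <- if (bare) volume else volume$voxels
  nz <- dim(x)[1]
  keep <- seq_len(nz) >= max(1, ceiling(w[1] * nz)) &
          seq_len(nz) <= floor(w[2] * nz)
  x[!keep, , ] <- 0
  if (bare) return(x)
  volume$voxels <- x
  if (!is.null(volume$body_mask)) volume$body_mask[!keep, , ] <- FALSE
  if (!is.null(volume$region_masks))
    volume$region_masks <- lapply(volume$region_masks, function(m) {
      m[!keep, , ] <- FALSE
      m
    })
  volume
}
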