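`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
with_rng_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(expr)
}

# Endpoint-aligned source coordinates for resampling n_out points from n_in.
resample_coords <- function(n_in, n_out) {
  if (n_out == 1) return((n_in + 1) / 2)
  1 + (seq_len(n_out) - 1) * (n_in - 1) / (n_out - 1)
}

#' Trilinear resize of a 3D volume
#'
#' Resamples a volume to new grid dimensions with endpoint-aligned trilinear
#' interpolation (so resizing to the input dimensions is the identity).  An
#' optional Gaussian pre-smoothing pass can be enabled when downsampling.
#'
#' @param x 3D numeric array.
#' @param out_dims integer vector of length 3.
#' @param antialias if `TRUE`, Gaussian-presmooth axes that are being shrunk.
#' @return 3D numeric array with dimensions `out_dims`.
#' @export
resize_volume <- function(x, out_dims, antialias = FALSE) {
  d <- dim(x)
  stopifnot(length(d) == 3, length(out_dims) == 3)
  out_dims <- as.integer(out_dims)
  if (any(out_dims < 1)) stop("output dimensions must be positive")
  if (all(d == out_dims)) return(x)
  if (antialias) {
    ratio <- d / out_dims
    sig <- ifelse(ratio > 1, 0.5 * (ratio - 1), 0)
    if (any(sig > 0)) x <- array(cpp_gaussian_blur3d(as.double(x), d, max(sig)), d)
  }
  cd <- resample_coords(d[1], out_dims[1])
  ch <- resample_coords(d[2], out_dims[2])
  cw <- resample_coords(d[3], out_dims[3])
  coords <- cbind(rep(cd, times = out_dims[2] * out_dims[3]),
                  rep(rep(ch, each = out_dims[1]), times = out_dims[3]),
                  rep(cw, each = out_dims[1] * out_dims[2]))
  array(cpp_trilinear_sample(as.double(x), d, coords), out_dims)
}

# Nearest-neighbour resize for binary masks (index subsetting; exact).
resize_mask <- function(mask, out_dims) {
  d <- dim(mask)
  if (all(d == out_dims)) return(mask)
  i1 <- pmin(pmax(round(resample_coords(d[1], out_dims[1])), 1), d[1])
  i2 <- pmin(pmax(round(resample_coords(d[2], out_dims[2])), 1), d[2])
  i3 <- pmin(pmax(round(resample_coords(d[3], out_dims[3])), 1), d[3])
  mask[i1, i2, i3, drop = FALSE]
}

# Gaussian blur wrapper.
blur_volume <- function(x, sigma) {
  array(cpp_gaussian_blur3d(as.double(x), dim(x), sigma), dim(x))
}

# Largest 6-connected component of a binary mask.
largest_component <- function(mask) {
  d <- dim(mask)
  lab <- cpp_label_components(as.logical(mask), d)
  if (all(lab == 0L)) return(array(FALSE, d))
  best <- as.integer(names(which.max(table(lab[lab > 0L]))))
  array(lab == best, d)
}

# Integer shift of a 3D array with zero fill.
shift_volume <- function(x, shift, fill = 0) {
  d <- dim(x)
  out <- array(fill, d)
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    s <- shift[a]
    if (abs(s) >= d[a]) return(out)
    if (s >= 0) { src[[a]] <- 1:(d[a] - s); dst[[a]] <- (1 + s):d[a] }
    else { src[[a]] <- (1 - s):d[a]; dst[[a]] <- 1:(d[a] + s) }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- x[src[[1]], src[[2]], src[[3]]]
  out
}

# Rotate a volume by `angle` degrees about one grid axis (1 = vertical),
# resampling trilinearly about the grid centre.  Background fills with 0.
rotate_volume <- function(x, axis, angle) {
  if (angle == 0) return(x)
  d <- dim(x)
  th <- angle * pi / 180
  ctr <- (d + 1) / 2
  g <- expand.grid(d1 = seq_len(d[1]), d2 = seq_len(d[2]), d3 = seq_len(d[3]))
  p <- sweep(as.matrix(g), 2, ctr)
  ax <- setdiff(1:3, axis)
  rot <- p
  rot[, ax[1]] <- cos(th) * p[, ax[1]] - sin(th) * p[, ax[2]]
  rot[, ax[2]] <- sin(th) * p[, ax[1]] + cos(th) * p[, ax[2]]
  coords <- sweep(rot, 2, ctr, `+`)
  array(cpp_trilinear_sample(as.double(x), d, coords), d)
}
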