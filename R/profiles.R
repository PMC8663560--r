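#' Grid profiles
#'
#' A profile fixes the voxel-grid geometry of the pipeline.  The `"paper"`
#' profile uses the clinical whole-body grid: variable 90--120 transverse
#' slices at acquisition, vertically interpolated to 95 x 150 x 250 and then
#' downsampled to 85 x 110 x 135 voxels.  The `"tiny"` profile scales the
#' in-plane axes by roughly 1/8 and the vertical axis by roughly 1/4
#' (24 x 19 x 31 -> 22 x 14 x 17); the vertical axis keeps more of its scale
#' because it carries the upper/lower abdominal depot distinction, which
#' must stay resolvable after the network's four pooling stages.  Training
#' at this scale runs in minutes on one CPU.
#'
#' Voxel spacing is derived from nominal physical extents (10 mm slices,
#' 450 mm anterior-posterior and 600 mm left-right fields of view) so that
#' compartment volumes come out in litre-like units.
#'
#' @param name `"tiny"` or `"paper"`.
#' @return A list with elements `name`, `inplane` (native in-plane dims),
#'   `target_dims` (after vertical interpolation), `final_dims` (network
#'   input grid) and `spacing` (mm per voxel on the native grid).
#' @export
grid_profile <- function(name = c("tiny", "paper")) {
  name <- match.arg(name)
  p <- switch(name,
    paper = list(inplane = c(150L, 250L),
                 target_dims = c(95L, 150L, 250L),
                 final_dims  = c(85L, 110L, 135L)),
    tiny  = list(inplane = c(19L, 31L),
                 target_dims = c(24L, 19L, 31L),
                 final_dims  = c(22L, 14L, 17L)))
  p$name <- name
  p$spacing <- c(10, 450 / p$inplane[1], 600 / p$inplane[2])
  p
}
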