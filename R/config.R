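#' Load the pipeline configuration
#'
#' Reads the package's recorded defaults (`inst/config/default.yaml`),
#' optionally overlays a user YAML file, and attaches the requested grid
#' profile.  The configuration is the single source of every tunable
#' parameter in the pipeline; seeds are supplied per call.
#'
#' @param profile `"tiny"` (desk-scale default) or `"paper"` (clinical grid).
#' @param path optional user YAML whose entries override the defaults.
#' @return Nested configuration list with a `grid` element.
#' @export
default_config <- function(profile = c("tiny", "paper"), path = NULL) {
  profile <- match.arg(profile)
  cfg <- yaml::read_yaml(system.file("config", "default.yaml",
                                     package = "adiponet", mustWork = TRUE))
  if (!is.null(path)) cfg <- modify_list_deep(cfg, yaml::read_yaml(path))
  cfg$profile <- profile
  cfg$grid <- grid_profile(profile)
  cfg
}

modify_list_deep <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- modify_list_deep(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}
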