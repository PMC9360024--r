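#' Default analysis configuration
#'
#' Flat key-value configuration shared by the pipeline stages: buffer radii,
#' cell size, primary radius, inequality category thresholds, landscape
#' binarization threshold and connectivity, and the seasonal SD convention.
#'
#' @param ... overrides for individual keys.
#' @return a named list of class `gx_config`, validated against the schema.
#' @export
gx_config <- function(...) {
  cfg <- list(radii = c(500, 1000, 1500),
              primary_radius = 500,
              cell_size = 100,
              gini_thresholds = c(0.3, 0.5),
              binarize_threshold = 0.5,
              connectivity = 8,
              sd_convention = "population")
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validate_config(cfg)
  structure(cfg, class = "gx_config")
}

#' Read a configuration file
#'
#' A flat YAML key-value document; keys are checked against the schema at
#' load time, unknown keys are an error.
#'
#' @param path YAML file path.
#' @return a `gx_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(gx_config, raw)
}

validate_config <- function(cfg) {
  stopifnot(is.numeric(cfg$radii), length(cfg$radii) >= 1, all(cfg$radii >= 0),
            is.numeric(cfg$primary_radius), cfg$primary_radius >= 0,
            is.numeric(cfg$cell_size), cfg$cell_size > 0,
            length(cfg$gini_thresholds) == 2,
            cfg$gini_thresholds[1] < cfg$gini_thresholds[2],
            cfg$binarize_threshold >= 0, cfg$binarize_threshold <= 1,
            cfg$connectivity %in% c(4, 8),
            cfg$sd_convention %in% c("population", "sample"))
  invisible(TRUE)
}
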