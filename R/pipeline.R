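#' Simulate a complete synthetic study scene
#'
#' One landscape raster pair (greenspace + population), a rectangular
#' pseudo-city zone grid, and a four-season phenology stack — everything the
#' downstream exposure/inequality/seasonal/driver stages consume, generated
#' deterministically from one seed.
#'
#' @param seed integer master seed.
#' @param shape raster shape (rows, cols).
#' @param cell_size metres per cell.
#' @param n_zones_side zones per side (total `n_zones_side^2` cities).
#' @param target_coverage mean greenspace fraction.
#' @param pop_total total population of the scene.
#' @param pop_green_corr population-greenspace coupling in `[-1, 1]`.
#' @param correlation_length autocorrelation scale (m).
#' @param pop_clustering lognormal sigma of population intensity.
#' @param seasonal a [seasonal_params]; defaults to a half-deciduous
#'   landscape with strong winter leaf-off.
#' @return list: `green`, `pop` (grids), `zones` (a [zone_set]),
#'   `stack` (seasonal grids), `params`.
#' @export
simulate_scene <- function(seed = 1L, shape = c(256, 256), cell_size = 100,
                           n_zones_side = 10, target_coverage = 0.35,
                           pop_total = 1000000L, pop_green_corr = -0.3,
                           correlation_length = 800, pop_clustering = 1,
                           seasonal = seasonal_params(seed = seed)) {
  lp <- landscape_params(shape = shape, cell_size = cell_size,
                         correlation_length = correlation_length,
                         target_coverage = target_coverage,
                         pop_total = pop_total,
                         pop_clustering = pop_clustering,
                         pop_green_corr = pop_green_corr, seed = seed)
  green <- gen_greenspace(lp)
  pop <- gen_population(lp, green)
  zones <- rect_zones(green, n_zones_side, n_zones_side)
  stack <- gen_seasonal_stack(green, seasonal)
  list(green = green, pop = pop, zones = zones, stack = stack,
       params = list(landscape = lp, seasonal = seasonal))
}

#' Run the full analysis pipeline and write its outputs
#'
#' Simulates a scene, then runs every stage — exposure, inequality,
#' seasonal statistics, landscape metrics and driver attribution — writing
#' rasters, zones, a parameter manifest and one CSV per stage into
#' `out_dir`. Deterministic: identical seeds produce byte-identical CSVs.
#'
#' Non-landscape covariates of the driver table (topography, climate,
#' socioeconomic) have no counterpart in the simulated rasters and are drawn
#' from the canonical covariate distributions; the landscape covariates
#' (gcr, patch statistics, edge density) and the response are computed from
#' the scene itself.
#'
#' @param out_dir output directory (created if missing).
#' @param seed integer master seed.
#' @param config a [gx_config].
#' @param ... passed to [simulate_scene].
#' @return invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(out_dir, seed = 1L, config = gx_config(), ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  scene <- simulate_scene(seed = seed, cell_size = config$cell_size, ...)
  write_grid(scene$green, file.path(out_dir, "greenspace.asc"))
  write_grid(scene$pop, file.path(out_dir, "population.asc"))
  write_zones(scene$zones, file.path(out_dir, "zones.geojson"))
  manifest <- list(seed = seed, config = unclass(config),
                   landscape = unclass(scene$params$landscape),
                   seasonal = unclass(scene$params$seasonal),
                   r_version = paste(R.version$major, R.version$minor,
                                     sep = "."),
                   package_version =
                     as.character(utils::packageVersion("greenexposure")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  radii <- unique(c(config$primary_radius, config$radii))
  expo <- exposure_report(scene$green, scene$pop, scene$zones, radii)
  utils::write.csv(as.data.frame(expo),
                   file.path(out_dir, "exposure.csv"), row.names = FALSE)

  ineq <- inequality_report(expo, config$gini_thresholds)
  utils::write.csv(ineq, file.path(out_dir, "inequality.csv"),
                   row.names = FALSE)

  seas <- seasonal_report(scene$stack, scene$pop, scene$zones,
                          radius = config$primary_radius)
  utils::write.csv(seas, file.path(out_dir, "seasonal.csv"),
                   row.names = FALSE)

  tab <- scene_driver_table(scene, ineq, config, seed = seed)
  utils::write.csv(tab, file.path(out_dir, "drivers_table.csv"),
                   row.names = FALSE)
  tab_rs <- rescale_01(tab)
  scr <- screen_variables(tab_rs)
  utils::write.csv(scr$report, file.path(out_dir, "drivers_screening.csv"),
                   row.names = FALSE)
  models <- ols_nested(tab_rs)
  mtab <- do.call(rbind, lapply(names(models), function(nm) {
    cf <- models[[nm]]$coefficients
    cf$model <- nm
    cf$adj_r_squared <- models[[nm]]$adj_r_squared
    cf
  }))
  utils::write.csv(mtab, file.path(out_dir, "drivers_models.csv"),
                   row.names = FALSE)
  vp <- variance_partition(tab_rs)
  utils::write.csv(data.frame(fraction = c("unique_provision",
                                           "unique_configuration",
                                           "joint", "residual"),
                              value = c(vp$unique_a, vp$unique_b,
                                        vp$joint, vp$residual)),
                   file.path(out_dir, "drivers_partition.csv"),
                   row.names = FALSE)
  invisible(list(scene = scene, exposure = expo, inequality = ineq,
                 seasonal = seas, drivers = list(table = tab,
                                                 screening = scr,
                                                 models = models,
                                                 partition = vp)))
}

# Per-zone driver table from the simulated scene: response = zone Gini;
# landscape covariates measured from the binarized greenspace map; the
# geographic/topographic/climate/socioeconomic covariates are synthetic
# draws from the canonical distributions (seeded).
scene_driver_table <- function(scene, ineq, config, seed) {
  lab <- rasterize_zones(scene$zones, scene$green)
  bin <- binarize(scene$green, config$binarize_threshold)
  cs <- scene$green$cell_size
  ids <- zone_ids(scene$zones)
  land <- lapply(seq_along(ids), function(k) {
    v <- bin$values
    v[lab != k] <- NA_real_
    zb <- gx_grid(v, cell_size = cs, origin = bin$origin,
                  role = "greenspace", crs = bin$crs)
    zone_area <- sum(lab == k) * cs^2
    ls <- landscape_summary(label_patches(zb, config$connectivity),
                            zone_area)
    pop_z <- sum(scene$pop$values[lab == k], na.rm = TRUE)
    c(gcr = ls$gcr, mean_patch_size = ls$mean_patch_size,
      largest_patch_size = ls$largest_patch_size,
      pa_ratio = ls$mean_perimeter_area_ratio,
      shape_index = ls$mean_shape_index, ed = ls$edge_density,
      pop_density = pop_z / (zone_area / 1e6))
  })
  land <- as.data.frame(do.call(rbind, land))
  d <- covariate_distributions()
  synth_names <- c("lat", "lon", "elevation", "slope", "prcp", "temp",
                   "vpd", "ntl", "road_length")
  synth <- withr::with_seed(seed + 7L, {
    sapply(synth_names, function(nm) {
      j <- match(nm, d$covariate)
      pmin(pmax(stats::rnorm(length(ids), d$mean[j], d$sd[j]),
                d$min[j]), d$max[j])
    })
  })
  tab <- data.frame(city_id = ids, gini = ineq$gini, synth, land,
                    stringsAsFactors = FALSE)
  tab[!is.na(tab$gini), , drop = FALSE]
}
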