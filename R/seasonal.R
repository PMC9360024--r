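#' Meteorological season of a calendar month
#'
#' Northern hemisphere: Mar-May spring, Jun-Aug summer, Sep-Nov autumn,
#' Dec-Feb winter. Southern hemisphere is the opposite case: Sep-Nov spring,
#' Dec-Feb summer, Mar-May autumn, Jun-Aug winter.
#'
#' @param month integer 1-12.
#' @param hemisphere `"N"` or `"S"`.
#' @return one of `"spring"`, `"summer"`, `"autumn"`, `"winter"`.
#' @export
season_of <- function(month, hemisphere = c("N", "S")) {
  hemisphere <- match.arg(hemisphere)
  if (!is.numeric(month) || length(month) != 1L ||
      month < 1 || month > 12 || month != round(month))
    stop("'month' must be an integer in 1..12")
  north <- c("winter", "winter", "spring", "spring", "spring",
             "summer", "summer", "summer", "autumn", "autumn",
             "autumn", "winter")
  s <- north[month]
  if (hemisphere == "S") {
    flip <- c(spring = "autumn", summer = "winter",
              autumn = "spring", winter = "summer")
    s <- unname(flip[s])
  }
  s
}

#' Coefficient of spatial variation of exposure
#'
#' \eqn{csv = \sigma / \mu}: the population (not sample) standard deviation
#' of the zone's gridded exposure values divided by their mean — a
#' dimensionless measure of how unevenly greenspace exposure is spread in
#' space.
#'
#' @param exposure_cells per-cell buffered exposure values within the zone.
#' @return csv (>= 0).
#' @export
csv_stat <- function(exposure_cells) {
  x <- exposure_cells[!is.na(exposure_cells)]
  if (!length(x)) stop("no valid cells")
  mu <- mean(x)
  if (mu == 0) stop("zero-mean exposure: csv undefined")
  sqrt(mean((x - mu)^2)) / mu
}

#' Spatiotemporal variation of exposure over the four seasons
#'
#' The population standard deviation of the four seasonal csv values:
#' \eqn{cstv = std(\{csv_i : i = 1..4\})}. Zero when the seasons are
#' spatially identical in relative terms.
#'
#' @param csv_by_season numeric vector of exactly four seasonal csv values.
#' @return cstv (>= 0).
#' @export
cstv_stat <- function(csv_by_season) {
  x <- csv_by_season
  if (length(x) != 4L || anyNA(x))
    stop("need exactly four seasonal csv values")
  sqrt(mean((x - mean(x))^2))
}

#' Seasonal exposure and inequality report
#'
#' For every zone and season: population-weighted exposure GE^d, the Gini
#' index of exposure, and the coefficient of spatial variation csv; plus the
#' cross-season cstv and the summer-minus-winter Gini difference
#' `dGini_sw`. Each zone must declare a hemisphere attribute; a stack keyed
#' by season names is taken as already hemisphere-resolved, while a stack
#' keyed by calendar quarters (`"DJF"`, `"MAM"`, `"JJA"`, `"SON"`) is mapped
#' to seasons per zone via [season_of].
#'
#' @param green_by_season named list of four aligned greenspace grids, keyed
#'   either `spring/summer/autumn/winter` or `DJF/MAM/JJA/SON`.
#' @param pop population-role [gx_grid].
#' @param zones a [zone_set].
#' @param radius buffer radius in metres.
#' @return data.frame with one row per zone: per-season `GE_*`, `gini_*`,
#'   `csv_*`, plus `cstv`, `dGini_sw`, `dcsv_sw` and `flag`.
#' @export
seasonal_report <- function(green_by_season, pop, zones, radius = 500) {
  seasons <- c("spring", "summer", "autumn", "winter")
  quarters <- c("DJF", "MAM", "JJA", "SON")
  keys <- names(green_by_season)
  by_quarter <- all(sort(keys) == sort(quarters))
  if (!by_quarter && !all(sort(keys) == sort(seasons)))
    stop("'green_by_season' must be keyed by the four seasons or quarters")
  for (g in green_by_season) check_aligned(g, pop)
  template <- green_by_season[[1]]
  lab <- rasterize_zones(zones, template)
  gd <- lapply(green_by_season, focal_fraction, radius_m = radius)
  hemis <- vapply(zones$zones, function(z) as.character(z$hemisphere),
                  character(1))
  # quarter -> season mapping per hemisphere (mid-month of each quarter)
  q_mid <- c(DJF = 1, MAM = 4, JJA = 7, SON = 10)
  rows <- lapply(seq_along(zones$zones), function(k) {
    zid <- zone_ids(zones)[k]
    hemi <- hemis[k]
    out <- stats::setNames(
      as.list(rep(NA_real_, 3L * 4L + 3L)),
      c(paste0("GE_", seasons), paste0("gini_", seasons),
        paste0("csv_", seasons), "cstv", "dGini_sw", "dcsv_sw"))
    out <- c(list(zone_id = zid), out, list(flag = NA_character_))
    tryCatch({
      if (is.na(hemi) || !hemi %in% c("N", "S"))
        stop("zone '", zid, "' must declare hemisphere 'N' or 'S'")
      key_of <- if (by_quarter) {
        sm <- vapply(quarters, function(q) season_of(q_mid[[q]], hemi),
                     character(1))
        stats::setNames(quarters, sm)   # season -> quarter key
      } else stats::setNames(seasons, seasons)
      mask <- lab == k
      if (!any(mask & !is.na(template$values)))
        stop("empty zone: '", zid, "'")
      for (s in seasons) {
        gds <- gd[[key_of[[s]]]]
        out[[paste0("GE_", s)]] <-
          population_weighted_exposure(pop, gds, mask, zid)
        sel <- mask & !is.na(gds$values) & !is.na(pop$values)
        out[[paste0("gini_", s)]] <-
          as.numeric(gini(gds$values[sel], pop$values[sel]))
        out[[paste0("csv_", s)]] <- csv_stat(gds$values[sel])
      }
      out$cstv <- cstv_stat(unlist(out[paste0("csv_", seasons)]))
      out$dGini_sw <- out$gini_summer - out$gini_winter
      out$dcsv_sw <- out$csv_summer - out$csv_winter
    }, error = function(e) out$flag <<- conditionMessage(e))
    as.data.frame(out, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
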