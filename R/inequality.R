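#' Population-weighted Lorenz curve of greenspace exposure
#'
#' Cells are sorted by exposure value (ascending; ties keep input order) and
#' the cumulative share of population (x) is plotted against the cumulative
#' share of population-weighted exposure (y), from (0, 0) to (1, 1). A curve
#' on the diagonal means everyone experiences the same exposure.
#'
#' @param values per-cell exposure values.
#' @param weights per-cell population weights (>= 0, positive total).
#' @return data.frame with columns `cum_pop` and `cum_exposure`, starting at
#'   (0, 0).
#' @export
lorenz_curve <- function(values, weights) {
  if (length(values) != length(weights))
    stop("'values' and 'weights' must have equal length")
  if (any(weights < 0)) stop("negative weight")
  W <- sum(weights)
  if (W == 0) stop("total weight is zero")
  o <- order(values)             # stable: ties stay in cell-index order
  w <- weights[o]; v <- values[o]
  cw <- cumsum(w) / W
  tot <- sum(w * v)
  cy <- if (tot > 0) cumsum(w * v) / tot else cumsum(w * v)
  data.frame(cum_pop = c(0, cw), cum_exposure = c(0, cy))
}

#' Weighted Gini index
#'
#' One minus twice the trapezoidal area under the population-weighted Lorenz
#' curve: 0 is absolute equality (everyone the same exposure), 1 absolute
#' inequality. When the total weighted exposure is zero the index is
#' reported as 0 with the `degenerate` attribute set, so batch runs over
#' many zones complete.
#'
#' @inheritParams lorenz_curve
#' @return the Gini index in `[0, 1]`, with attribute `degenerate`.
#' @export
gini <- function(values, weights = rep(1, length(values))) {
  if (length(values) != length(weights))
    stop("'values' and 'weights' must have equal length")
  if (any(weights < 0)) stop("negative weight")
  if (sum(weights) == 0) stop("total weight is zero")
  if (sum(weights * values) == 0)
    return(structure(0, degenerate = TRUE))
  lc <- lorenz_curve(values, weights)
  area <- sum(diff(lc$cum_pop) *
                (utils::head(lc$cum_exposure, -1) +
                   utils::tail(lc$cum_exposure, -1)) / 2)
  g <- 1 - 2 * area
  structure(min(max(g, 0), 1), degenerate = FALSE)
}

#' Categorize an inequality level
#'
#' Half-open intervals: `low` below `t_low`, `medium` in
#' `[t_low, t_high)`, `high` at or above `t_high`.
#'
#' @param gini Gini index value in `[0, 1]`.
#' @param thresholds length-2 numeric `(t_low, t_high)` with
#'   `0 <= t_low < t_high <= 1`. The defaults bracket the typical range of
#'   city-level exposure Ginis (regional means roughly 0.2-0.5).
#' @return one of `"low"`, `"medium"`, `"high"`.
#' @export
classify_inequality <- function(gini, thresholds = c(0.3, 0.5)) {
  t_low <- thresholds[1]; t_high <- thresholds[2]
  if (!(t_low >= 0 && t_low < t_high && t_high <= 1))
    stop("invalid thresholds: need 0 <= t_low < t_high <= 1")
  if (gini < t_low) "low" else if (gini < t_high) "medium" else "high"
}

#' Gini of exposure for one zone
#'
#' Applies the weighted Gini to the zone's per-cell (exposure, population)
#' pairs at the primary buffer radius, recorded by [exposure_report].
#'
#' @param exposure one element of a `gx_exposure` report (a per-zone result
#'   with `cell_pairs`).
#' @param thresholds passed to [classify_inequality].
#' @return a list of class `gini_result`: `zone_id`, `gini`, `lorenz`,
#'   `degenerate`, `category`.
#' @export
zone_gini <- function(exposure, thresholds = c(0.3, 0.5)) {
  cp <- exposure$cell_pairs
  if (is.null(cp)) stop("exposure result for zone '", exposure$zone_id,
                        "' carries no cell pairs (flag: ", exposure$flag, ")")
  if (sum(cp$P > 0) < 2L)
    stop("insufficient cells: zone '", exposure$zone_id,
         "' has fewer than 2 positively weighted cells")
  g <- gini(cp$G, cp$P)
  structure(list(zone_id = exposure$zone_id,
                 gini = as.numeric(g),
                 lorenz = lorenz_curve(cp$G, cp$P),
                 degenerate = attr(g, "degenerate"),
                 category = classify_inequality(as.numeric(g), thresholds)),
            class = "gini_result")
}

#' @export
print.gini_result <- function(x, ...) {
  cat(sprintf("<gini_result> zone %s: Gini %.4f (%s%s)\n", x$zone_id,
              x$gini, x$category, if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' Plot a Lorenz curve
#'
#' @param x a `gini_result`.
#' @param ... passed to [graphics::plot].
#' @export
plot.gini_result <- function(x, ...) {
  graphics::plot(x$lorenz$cum_pop, x$lorenz$cum_exposure, type = "l",
                 xlab = "Cumulative population share",
                 ylab = "Cumulative exposure share",
                 main = sprintf("Zone %s: Gini = %.3f", x$zone_id, x$gini),
                 ...)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  invisible(x)
}

#' Gini table for every zone of an exposure report
#'
#' @param results a `gx_exposure` object.
#' @param thresholds passed to [classify_inequality].
#' @return data.frame: `zone_id`, `gini`, `category`, `degenerate`, `flag`.
#' @export
inequality_report <- function(results, thresholds = c(0.3, 0.5)) {
  rows <- lapply(results, function(z) {
    out <- data.frame(zone_id = z$zone_id, gini = NA_real_,
                      category = NA_character_, degenerate = NA,
                      flag = z$flag, stringsAsFactors = FALSE)
    if (is.na(z$flag)) {
      zg <- tryCatch(zone_gini(z, thresholds), error = function(e) NULL)
      if (is.null(zg)) out$flag <- "insufficient cells"
      else {
        out$gini <- zg$gini; out$category <- zg$category
        out$degenerate <- zg$degenerate
      }
    }
    out
  })
  do.call(rbind, rows)
}
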