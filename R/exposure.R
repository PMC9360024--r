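#' Aggregate a binary greenspace map to a fractional grid
#'
#' Each coarse cell is the mean of its `factor` x `factor` block of fine
#' cells over the valid (non-nodata) ones, turning a fine binary
#' greenspace/not map into the mean fractional greenspace coverage at the
#' coarser resolution. A coarse cell is nodata only when its whole block is
#' nodata. Dimensions must divide exactly; no implicit padding.
#'
#' @param fine a [gx_grid] with values in `{0, 1}` on valid cells.
#' @param factor integer aggregation factor (e.g. 10 for 10 m to 100 m).
#' @return a greenspace-role [gx_grid] with
#'   `cell_size = fine$cell_size * factor`.
#' @export
aggregate_fraction <- function(fine, factor) {
  stopifnot(inherits(fine, "gx_grid"))
  factor <- as.integer(factor)
  if (factor < 1L) stop("'factor' must be a positive integer")
  v <- fine$values
  nr <- nrow(v); nc <- ncol(v)
  if (nr %% factor != 0L || nc %% factor != 0L)
    stop("grid dimensions (", nr, " x ", nc,
         ") are not divisible by factor ", factor, "; no implicit padding")
  vv <- v[!is.na(v)]
  if (length(vv) && !all(vv %in% c(0, 1)))
    stop("'fine' must be binary {0, 1} on valid cells")
  nrc <- nr %/% factor; ncc <- nc %/% factor
  # block index for every fine cell, then grouped sums
  bi <- (rep(seq_len(nr), times = nc) - 1L) %/% factor
  bj <- (rep(seq_len(nc), each = nr) - 1L) %/% factor
  block <- bi + nrc * bj + 1L
  valid <- !is.na(v)
  sums <- rowsum_fill(as.vector(ifelse(valid, v, 0)), block, nrc * ncc)
  cnts <- rowsum_fill(as.vector(valid) + 0, block, nrc * ncc)
  out <- ifelse(cnts > 0, sums / pmax(cnts, 1), NA_real_)
  gx_grid(matrix(out, nrc, ncc), cell_size = fine$cell_size * factor,
          origin = fine$origin, role = "greenspace", crs = fine$crs)
}

rowsum_fill <- function(x, group, n) {
  out <- numeric(n)
  s <- rowsum(x, group)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Buffered greenspace fraction (focal circular-kernel mean)
#'
#' Computes \eqn{G^d_i}: for each cell, the mean greenspace fraction over
#' all cells whose center lies within Euclidean distance `radius_m`
#' (inclusive) of that cell's center — a resident's "nearby green
#' environment". At grid edges and next to nodata cells the kernel is
#' renormalized over the available cells, so no artificial suppression of
#' exposure occurs at city fringes. A radius smaller than the cell size
#' leaves the grid unchanged (kernel = center cell only).
#'
#' @param green a greenspace-role [gx_grid].
#' @param radius_m buffer radius in metres (>= 0).
#' @return a [gx_grid] of buffered fractions, nodata preserved.
#' @export
focal_fraction <- function(green, radius_m) {
  stopifnot(inherits(green, "gx_grid"))
  if (radius_m < 0) stop("'radius_m' must be >= 0")
  v <- green$values
  cs <- green$cell_size
  r_cells <- floor(radius_m / cs + 1e-9)
  if (r_cells == 0L) return(green)
  off <- expand.grid(di = -r_cells:r_cells, dj = -r_cells:r_cells)
  keep <- sqrt(off$di^2 + off$dj^2) * cs <= radius_m + 1e-9 * cs
  off <- off[keep, , drop = FALSE]
  valid <- !is.na(v)
  vz <- ifelse(valid, v, 0)
  nr <- nrow(v); nc <- ncol(v)
  num <- matrix(0, nr, nc); den <- matrix(0, nr, nc)
  for (k in seq_len(nrow(off))) {
    di <- off$di[k]; dj <- off$dj[k]
    ri <- max(1, 1 - di):min(nr, nr - di)   # rows receiving a contribution
    cj <- max(1, 1 - dj):min(nc, nc - dj)
    num[ri, cj] <- num[ri, cj] + vz[ri + di, cj + dj]
    den[ri, cj] <- den[ri, cj] + valid[ri + di, cj + dj]
  }
  out <- ifelse(den > 0, num / pmax(den, 1), NA_real_)
  out[!valid] <- NA_real_
  out <- pmin(pmax(out, 0), 1)   # guard float round-off at [0,1] bounds
  gx_grid(out, cell_size = cs, origin = green$origin,
          role = "greenspace", crs = green$crs)
}

#' Physical greenspace coverage rate of a zone
#'
#' \deqn{GC = \sum_i G_i / N} over the N valid cells of the zone: the plain
#' mean greenspace fraction, ignoring where people live.
#'
#' @param green a greenspace-role [gx_grid].
#' @param zone_mask logical or integer matrix selecting the zone's cells
#'   (non-zero/`TRUE` = in zone).
#' @param zone_id identifier used in error messages.
#' @return GC as a fraction in `[0, 1]`.
#' @export
greenspace_coverage <- function(green, zone_mask, zone_id = "zone") {
  sel <- (zone_mask != 0) & !is.na(green$values)
  if (!any(sel)) stop("empty zone: '", zone_id, "' has no valid cells")
  mean(green$values[sel])
}

#' Population-weighted greenspace exposure of a zone
#'
#' \deqn{GE^d = \sum_i P_i G^d_i / \sum_i P_i} over the valid cells of the
#' zone: the buffered greenspace fraction averaged with population weights,
#' so cells where more people reside count proportionately more.
#'
#' @param pop a population-role [gx_grid].
#' @param green_d a [gx_grid] of buffered greenspace fractions
#'   (see [focal_fraction]).
#' @param zone_mask logical or integer matrix selecting the zone's cells.
#' @param zone_id identifier used in error messages.
#' @return GE^d as a fraction in `[0, 1]`.
#' @export
population_weighted_exposure <- function(pop, green_d, zone_mask,
                                         zone_id = "zone") {
  check_aligned(pop, green_d)
  sel <- (zone_mask != 0) & !is.na(green_d$values) & !is.na(pop$values)
  if (!any(sel)) stop("empty zone: '", zone_id, "' has no valid cells")
  p <- pop$values[sel]
  w <- sum(p)
  if (w <= 0)
    stop("no population in zone '", zone_id, "': exposure is undefined")
  sum(p * green_d$values[sel]) / w
}

#' Per-zone exposure report
#'
#' For every zone: physical coverage GC, population-weighted exposure GE^d
#' for each buffer radius, population total, valid-cell count, and the
#' per-cell (P_i, G^d_i) pairs for the first (primary) radius that feed the
#' Gini computation. The buffered fraction is computed over the full raster
#' before zonal masking, so greenspace outside a zone but within the buffer
#' still contributes to the exposure of in-zone residents. Zones failing a
#' precondition (no valid cells, zero population) are reported with an error
#' flag rather than dropped.
#'
#' @param green a greenspace-role [gx_grid].
#' @param pop a population-role [gx_grid] aligned with `green`.
#' @param zones a [zone_set] (or a precomputed labelled mask from
#'   [rasterize_zones]).
#' @param radii numeric vector of buffer radii in metres; the first is the
#'   primary radius.
#' @return an object of class `gx_exposure`: a list of per-zone results,
#'   each with `zone_id`, `GC`, `GE_by_radius`, `n_cells`, `pop_total`,
#'   `cell_pairs` (data.frame `P`, `G`), and `flag` (`NA` or the error
#'   message). Use [as.data.frame()] for the tabular view.
#' @export
exposure_report <- function(green, pop, zones, radii = c(500, 1000, 1500)) {
  if (!length(radii)) stop("'radii' must be non-empty")
  check_aligned(green, pop)
  lab <- if (is.matrix(zones)) zones else rasterize_zones(zones, green)
  ids <- attr(lab, "zone_ids")
  if (is.null(ids)) ids <- as.character(sort(unique(lab[lab != 0])))
  gd <- lapply(radii, function(r) focal_fraction(green, r))
  names(gd) <- as.character(radii)
  res <- lapply(seq_along(ids), function(k) {
    zid <- ids[k]
    mask <- lab == k
    out <- list(zone_id = zid, GC = NA_real_,
                GE_by_radius = stats::setNames(rep(NA_real_, length(radii)),
                                               as.character(radii)),
                n_cells = sum(mask & !is.na(green$values)),
                pop_total = NA_real_, cell_pairs = NULL, flag = NA_character_)
    tryCatch({
      out$GC <- greenspace_coverage(green, mask, zid)
      sel <- mask & !is.na(green$values) & !is.na(pop$values)
      out$pop_total <- sum(pop$values[sel])
      for (r in as.character(radii))
        out$GE_by_radius[[r]] <-
          population_weighted_exposure(pop, gd[[r]], mask, zid)
      prim <- as.character(radii[1])
      out$cell_pairs <- data.frame(P = pop$values[sel],
                                   G = gd[[prim]]$values[sel])
    }, error = function(e) out$flag <<- conditionMessage(e))
    out
  })
  structure(res, class = "gx_exposure", radii = radii)
}

#' @export
as.data.frame.gx_exposure <- function(x, ...) {
  radii <- attr(x, "radii")
  ge <- do.call(rbind, lapply(x, function(z) z$GE_by_radius))
  colnames(ge) <- paste0("GE_", radii)
  df <- data.frame(zone_id = vapply(x, `[[`, character(1), "zone_id"),
                   GC = vapply(x, `[[`, numeric(1), "GC"),
                   ge,
                   pop_total = vapply(x, `[[`, numeric(1), "pop_total"),
                   n_cells = vapply(x, `[[`, numeric(1), "n_cells"),
                   flag = vapply(x, `[[`, character(1), "flag"),
                   stringsAsFactors = FALSE, row.names = NULL)
  df
}

#' Mean absolute exposure discrepancy between two buffer radii
#'
#' Across zones, the mean of `|GE^d1 - GE^d2|`, in percentage points — the
#' sensitivity of the exposure assessment to the buffer-distance choice.
#' Zones flagged with errors are skipped.
#'
#' @param results a `gx_exposure` object from [exposure_report].
#' @param d1,d2 radii in metres; both must be present in every result.
#' @return mean absolute discrepancy in percentage points.
#' @export
buffer_sensitivity <- function(results, d1, d2) {
  stopifnot(inherits(results, "gx_exposure"))
  ok <- Filter(function(z) is.na(z$flag), results)
  if (!length(ok)) stop("no zones with valid exposure results")
  d <- vapply(ok, function(z) {
    k1 <- as.character(d1); k2 <- as.character(d2)
    if (!k1 %in% names(z$GE_by_radius) || !k2 %in% names(z$GE_by_radius))
      stop("radius ", d1, " or ", d2, " missing from exposure results")
    abs(z$GE_by_radius[[k1]] - z$GE_by_radius[[k2]])
  }, numeric(1))
  mean(d) * 100
}
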