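#' Binarize a fractional greenspace grid
#'
#' Cell becomes 1 when its fraction is at or above `threshold`; nodata is
#' propagated.
#'
#' @param green a greenspace-role [gx_grid].
#' @param threshold in `[0, 1]`; default 0.5.
#' @return a [gx_grid] of `{0, 1}` values.
#' @export
binarize <- function(green, threshold = 0.5) {
  stopifnot(inherits(green, "gx_grid"))
  if (threshold < 0 || threshold > 1) stop("'threshold' must be in [0, 1]")
  v <- ifelse(is.na(green$values), NA_real_,
              as.numeric(green$values >= threshold))
  gx_grid(v, cell_size = green$cell_size, origin = green$origin,
          role = "greenspace", crs = green$crs)
}

#' Label greenspace patches
#'
#' Connected components of the foreground (value 1) under 4- or
#' 8-connectivity. Per patch, the area is `n_cells * cell_size^2` and the
#' perimeter is the exposed cell-edge length: edges shared with background,
#' nodata, or the raster boundary all count as exposed (so clipped patches
#' keep a closed outline). Perimeter always uses the 4-neighbourhood,
#' regardless of the labelling connectivity.
#'
#' @param binary a [gx_grid] with values in `{0, 1}`.
#' @param connectivity 4 or 8 (default 8, the common landscape-ecology
#'   choice).
#' @return a list of class `patch_set`: `labels` (integer matrix, 0 =
#'   background), `area` and `perimeter` (numeric vectors, one entry per
#'   patch, in m2 and m), `cell_size`.
#' @export
label_patches <- function(binary, connectivity = 8) {
  stopifnot(inherits(binary, "gx_grid"), connectivity %in% c(4, 8))
  v <- binary$values
  vv <- v[!is.na(v)]
  if (length(vv) && !all(vv %in% c(0, 1)))
    stop("'binary' must contain only 0/1 on valid cells")
  nr <- nrow(v); nc <- ncol(v)
  fg <- !is.na(v) & v == 1
  labels <- matrix(0L, nr, nc)
  n_fg <- sum(fg)
  if (n_fg == 0L)
    return(structure(list(labels = labels, area = numeric(0),
                          perimeter = numeric(0),
                          cell_size = binary$cell_size),
                     class = "patch_set"))
  id <- matrix(0L, nr, nc)
  id[fg] <- seq_len(n_fg)
  # adjacency edges between foreground cells, via shifted index matrices
  edge_pairs <- function(di, dj) {
    ri <- seq_len(nr - abs(di)); cj <- seq_len(nc - abs(dj))
    a <- id[ri + max(di, 0), cj + max(dj, 0), drop = FALSE]
    b <- id[ri - min(di, 0), cj - min(dj, 0), drop = FALSE]
    ok <- a > 0L & b > 0L
    cbind(a[ok], b[ok])
  }
  shifts <- list(c(1, 0), c(0, 1))
  if (connectivity == 8) shifts <- c(shifts, list(c(1, 1), c(1, -1)))
  edges <- do.call(rbind, lapply(shifts, function(s) edge_pairs(s[1], s[2])))
  g <- igraph::make_empty_graph(n = n_fg, directed = FALSE)
  if (!is.null(edges) && nrow(edges))
    g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  labels[fg] <- comp
  # exposed 4-edges per cell: neighbours that are background/nodata/out
  fg_pad <- matrix(FALSE, nr + 2L, nc + 2L)
  fg_pad[2:(nr + 1), 2:(nc + 1)] <- fg
  inner <- function(di, dj) fg_pad[2:(nr + 1) + di, 2:(nc + 1) + dj]
  exposed <- (4 - (inner(1, 0) + inner(-1, 0) + inner(0, 1) + inner(0, -1)))
  per_cell <- exposed * binary$cell_size
  per_cell[!fg] <- 0
  n_patch <- max(comp)
  area <- as.numeric(tabulate(comp, n_patch)) * binary$cell_size^2
  perimeter <- as.numeric(rowsum(per_cell[fg], comp)[, 1])
  structure(list(labels = labels, area = area, perimeter = perimeter,
                 cell_size = binary$cell_size),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set> %d patches, total area %.6g m2\n",
              length(x$area), sum(x$area)))
  invisible(x)
}

#' Landscape summary metrics for a zone
#'
#' Computes the landscape covariates of the driver analysis from a labelled
#' patch set: greenspace coverage rate (composition) and five configuration
#' metrics. The per-patch shape index is \eqn{0.25 P / \sqrt{A}} (1 for a
#' solid square, larger for more convoluted shapes). Edge density is the
#' total patch perimeter per unit zone area, reported in m/ha.
#'
#' @param patches a [label_patches] result.
#' @param zone_area_m2 area of the zone in m2 (> 0).
#' @return named list: `gcr` (fraction), `mean_patch_size` and
#'   `largest_patch_size` (m2), `largest_patch_index` (largest/zone area),
#'   `mean_perimeter_area_ratio` (m/m2), `mean_shape_index`
#'   (dimensionless), `edge_density` (m/ha). All zero when there are no
#'   patches.
#' @export
landscape_summary <- function(patches, zone_area_m2) {
  stopifnot(inherits(patches, "patch_set"))
  if (zone_area_m2 <= 0) stop("'zone_area_m2' must be > 0")
  n <- length(patches$area)
  if (n == 0L)
    return(list(gcr = 0, mean_patch_size = 0, largest_patch_size = 0,
                largest_patch_index = 0, mean_perimeter_area_ratio = 0,
                mean_shape_index = 0, edge_density = 0))
  A <- patches$area; P <- patches$perimeter
  list(gcr = sum(A) / zone_area_m2,
       mean_patch_size = mean(A),
       largest_patch_size = max(A),
       largest_patch_index = max(A) / zone_area_m2,
       mean_perimeter_area_ratio = mean(P / A),
       mean_shape_index = mean(0.25 * P / sqrt(A)),
       edge_density = sum(P) / (zone_area_m2 / 1e4))
}
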