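#' Construct a gridded raster
#'
#' A `gx_grid` is a georeferenced single-variable raster: a numeric matrix of
#' values (`NA` marks nodata), a square cell size in metres, the coordinate of
#' the top-left corner in a projected metric system, and the role the values
#' play. Greenspace-role grids hold the fractional greenspace coverage
#' \eqn{G_i \in [0,1]} of each cell; population-role grids hold non-negative
#' person counts \eqn{P_i}.
#'
#' @param values numeric matrix; `NA` encodes nodata.
#' @param cell_size cell edge length in metres (> 0).
#' @param origin numeric length-2, (x, y) of the top-left corner.
#' @param role one of `"greenspace"`, `"population"`, `"none"`; value-range
#'   constraints are enforced for the first two.
#' @param crs character WKT string for a projected metric CRS.
#' @return an object of class `gx_grid`.
#' @export
gx_grid <- function(values, cell_size, origin = c(0, 0),
                    role = c("none", "greenspace", "population"),
                    crs = gx_default_crs()) {
  role <- match.arg(role)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("'cell_size' must be a single positive number")
  if (length(origin) != 2L) stop("'origin' must be length 2 (x, y)")
  g <- structure(list(values = values, cell_size = as.numeric(cell_size),
                      origin = as.numeric(origin), role = role,
                      crs = crs),
                 class = "gx_grid")
  check_role_values(g)
  g
}

#' @export
print.gx_grid <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<gx_grid> %d x %d cells, %.6g m, role '%s'\n",
              nrow(x$values), ncol(x$values), x$cell_size, x$role))
  if (length(v))
    cat(sprintf("  valid cells: %d, range [%.4g, %.4g], mean %.4g\n",
                length(v), min(v), max(v), mean(v)))
  invisible(x)
}

#' @export
dim.gx_grid <- function(x) dim(x$values)

#' Nodata mask of a grid
#' @param grid a [gx_grid].
#' @return logical matrix, `TRUE` where the cell is nodata.
#' @export
nodata_mask <- function(grid) is.na(grid$values)

gx_default_crs <- function() {
  paste0('PROJCS["Local_Metric_Grid",GEOGCS["GCS_WGS_1984",',
         'DATUM["WGS_1984",SPHEROID["WGS_84",6378137,298.257223563]],',
         'PRIMEM["Greenwich",0],UNIT["Degree",0.0174532925199433]],',
         'PROJECTION["Transverse_Mercator"],UNIT["Meter",1]]')
}

check_role_values <- function(grid) {
  v <- grid$values[!is.na(grid$values)]
  if (grid$role == "greenspace" && length(v) &&
      (min(v) < 0 || max(v) > 1))
    stop("greenspace grid values must lie in [0, 1]; found range [",
         signif(min(v), 6), ", ", signif(max(v), 6), "]")
  if (grid$role == "population" && length(v) && min(v) < 0)
    stop("population grid values must be >= 0; found ", signif(min(v), 6))
  invisible(TRUE)
}

is_geographic_crs <- function(wkt) {
  grepl("^\\s*GEOGCS", wkt) || grepl("^\\s*GEOGCRS", wkt)
}

#' Check that two grids share cell size, extent and alignment
#'
#' All grids in one analysis must be on the same lattice; resampling is out of
#' scope, so a mismatch is an error rather than a silent interpolation.
#'
#' @param a,b [gx_grid] objects.
#' @return invisibly `TRUE`; errors on mismatch.
#' @export
check_aligned <- function(a, b) {
  if (!identical(dim(a$values), dim(b$values)))
    stop("grids are not aligned: dimensions differ")
  if (abs(a$cell_size - b$cell_size) > 1e-9 * max(a$cell_size, b$cell_size))
    stop("grids are not aligned: cell sizes differ")
  if (max(abs(a$origin - b$origin)) > 1e-6 * a$cell_size)
    stop("grids are not aligned: origins differ")
  invisible(TRUE)
}

# x/y coordinates of cell centers; rows run top-down from origin y.
cell_centers <- function(grid) {
  nr <- nrow(grid$values); nc <- ncol(grid$values); cs <- grid$cell_size
  list(x = grid$origin[1] + (seq_len(nc) - 0.5) * cs,
       y = grid$origin[2] - (seq_len(nr) - 0.5) * cs)
}

#' Read a single-band raster (ESRI ASCII grid)
#'
#' Reads `path` (an ESRI ASCII grid, the plain-text raster interchange format)
#' together with its `.prj` sidecar carrying the WKT coordinate reference
#' system. The buffer arithmetic downstream needs metres, so a raster without
#' a CRS, or one in a geographic (degree) CRS, is rejected.
#'
#' @param path path to the `.asc` file; the CRS is read from the file with the
#'   same stem and extension `.prj`.
#' @param role `"greenspace"` or `"population"`; out-of-range values for the
#'   declared role are an error.
#' @return a [gx_grid].
#' @export
read_grid <- function(path, role = c("greenspace", "population")) {
  role <- match.arg(role)
  if (!file.exists(path)) stop("no such raster: ", path)
  prj <- sub("\\.[^.]*$", ".prj", path)
  if (!file.exists(prj))
    stop("unreferenced raster: no CRS sidecar found at ", prj)
  crs <- paste(readLines(prj, warn = FALSE), collapse = "")
  if (is_geographic_crs(crs))
    stop("raster CRS is geographic (degrees); reproject to a projected ",
         "metric CRS before analysis (buffer distances are in metres)")
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("malformed ASCII grid header in ", path)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  if (length(vals) != nr * nc)
    stop("ASCII grid body has ", length(vals), " values, expected ", nr * nc)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  # header stores the lower-left corner; convert to top-left origin
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else 0
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else 0
  gx_grid(m, cell_size = hdr$cellsize,
          origin = c(xll, yll + nr * hdr$cellsize), role = role, crs = crs)
}

#' Write a grid as an ESRI ASCII raster
#'
#' Values are written with 9 significant digits (lossless at 32-bit float
#' precision); nodata cells are encoded with the header's `NODATA_value`. The
#' CRS is written to a `.prj` sidecar.
#'
#' @param grid a [gx_grid].
#' @param path output `.asc` path; the parent directory must exist.
#' @param nodata_value numeric sentinel used for nodata cells.
#' @return invisibly `path`.
#' @export
write_grid <- function(grid, path, nodata_value = -9999) {
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  v <- grid$values
  if (any(v[!is.na(v)] == nodata_value))
    stop("grid contains the nodata sentinel ", nodata_value, " as a value")
  nr <- nrow(v); nc <- ncol(v); cs <- grid$cell_size
  hdr <- c(sprintf("ncols %d", nc),
           sprintf("nrows %d", nr),
           sprintf("xllcorner %.10g", grid$origin[1]),
           sprintf("yllcorner %.10g", grid$origin[2] - nr * cs),
           sprintf("cellsize %.10g", cs),
           sprintf("NODATA_value %.10g", nodata_value))
  v[is.na(v)] <- nodata_value
  body <- apply(v, 1L, function(row) paste(sprintf("%.9g", row),
                                           collapse = " "))
  writeLines(c(hdr, body), path)
  writeLines(grid$crs, sub("\\.[^.]*$", ".prj", path))
  invisible(path)
}
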