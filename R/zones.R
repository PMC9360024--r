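#' Construct a zone set
#'
#' A `gx_zoneset` holds labelled polygons (country/state/county/city
#' stand-ins) in the same projected coordinate system as the grids they are
#' overlaid on. Each zone carries a unique `zone_id`, a simple (non-self-
#' intersecting) polygon, and attributes: `hemisphere` ("N"/"S", used to label
#' calendar seasons) and an optional `region_label`.
#'
#' @param zones list of zones; each a list with `zone_id`, `polygon` (a
#'   two-column matrix of x/y vertices, closed or open ring), `hemisphere`,
#'   and optionally `region_label`.
#' @return an object of class `gx_zoneset`.
#' @export
zone_set <- function(zones) {
  ids <- vapply(zones, function(z) as.character(z$zone_id), character(1))
  if (anyDuplicated(ids)) stop("zone_ids must be unique")
  zones <- lapply(zones, function(z) {
    p <- as.matrix(z$polygon)
    if (ncol(p) != 2L || nrow(p) < 3L)
      stop("zone '", z$zone_id, "': polygon needs >= 3 x/y vertices")
    # drop a closing vertex identical to the first
    if (all(p[nrow(p), ] == p[1L, ])) p <- p[-nrow(p), , drop = FALSE]
    if (!is_simple_polygon(p))
      stop("zone '", z$zone_id, "': polygon is self-intersecting")
    z$polygon <- p
    if (is.null(z$hemisphere)) z$hemisphere <- NA_character_
    z
  })
  structure(list(zones = zones), class = "gx_zoneset")
}

#' @export
print.gx_zoneset <- function(x, ...) {
  cat(sprintf("<gx_zoneset> %d zones\n", length(x$zones)))
  invisible(x)
}

#' @export
length.gx_zoneset <- function(x) length(x$zones)

zone_ids <- function(zones) {
  vapply(zones$zones, function(z) as.character(z$zone_id), character(1))
}

# O(n^2) segment-intersection test for simple polygons; polygons here are
# small administrative stand-ins, so quadratic cost is irrelevant.
is_simple_polygon <- function(p) {
  n <- nrow(p)
  seg <- cbind(p, p[c(2:n, 1L), , drop = FALSE])
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      # adjacent segments share an endpoint by construction
      if (j == i + 1L || (i == 1L && j == n)) next
      if (segments_cross(seg[i, 1:2], seg[i, 3:4], seg[j, 1:2], seg[j, 3:4]))
        return(FALSE)
    }
  }
  TRUE
}

segments_cross <- function(a1, a2, b1, b2) {
  d <- function(p, q, r) (q[1] - p[1]) * (r[2] - p[2]) -
    (q[2] - p[2]) * (r[1] - p[1])
  d1 <- d(b1, b2, a1); d2 <- d(b1, b2, a2)
  d3 <- d(a1, a2, b1); d4 <- d(a1, a2, b2)
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

#' Read zones from a GeoJSON FeatureCollection
#'
#' Features must be `Polygon` geometries (outer ring only; holes are not
#' supported for these administrative stand-ins) with a `zone_id` property,
#' a `hemisphere` property ("N"/"S") and an optional `region_label`.
#'
#' @param path path to a GeoJSON file.
#' @return a [zone_set].
#' @export
read_zones <- function(path) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$type) || gj$type != "FeatureCollection")
    stop("expected a GeoJSON FeatureCollection")
  zones <- lapply(gj$features, function(f) {
    if (f$geometry$type != "Polygon")
      stop("only Polygon geometries are supported")
    ring <- f$geometry$coordinates[[1]]
    p <- do.call(rbind, lapply(ring, function(xy) c(xy[[1]], xy[[2]])))
    list(zone_id = f$properties$zone_id,
         polygon = p,
         hemisphere = if (is.null(f$properties$hemisphere)) NA_character_
                      else f$properties$hemisphere,
         region_label = f$properties$region_label)
  })
  zone_set(zones)
}

#' Write zones as a GeoJSON FeatureCollection
#'
#' @param zones a [zone_set].
#' @param path output path.
#' @return invisibly `path`.
#' @export
write_zones <- function(zones, path) {
  feats <- lapply(zones$zones, function(z) {
    p <- z$polygon
    ring <- lapply(seq_len(nrow(p)), function(i) list(p[i, 1], p[i, 2]))
    ring[[length(ring) + 1L]] <- ring[[1L]]
    props <- list(zone_id = z$zone_id, hemisphere = z$hemisphere)
    if (!is.null(z$region_label)) props$region_label <- z$region_label
    list(type = "Feature",
         properties = props,
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Rasterize zones to a labelled mask
#'
#' Each cell of the template grid is assigned to the zone whose polygon
#' contains the cell's center (inclusive of the boundary, i.e. "covers"
#' semantics); cells in no zone get 0. When zones overlap, the earlier zone
#' in the list keeps the cell and a warning is emitted.
#'
#' @param zones a [zone_set].
#' @param template a [gx_grid] providing the lattice.
#' @return integer matrix of zone indices (0 = outside), with the zone ids as
#'   attribute `zone_ids` (index k labels `zone_ids[k]`).
#' @export
rasterize_zones <- function(zones, template) {
  cc <- cell_centers(template)
  nr <- nrow(template$values); nc <- ncol(template$values)
  xs <- rep(cc$x, each = nr)
  ys <- rep(cc$y, times = nc)
  lab <- matrix(0L, nr, nc)
  overlap <- FALSE
  for (k in seq_along(zones$zones)) {
    p <- zones$zones[[k]]$polygon
    # bounding-box prefilter keeps inpolygon calls small
    cand <- which(xs >= min(p[, 1]) & xs <= max(p[, 1]) &
                  ys >= min(p[, 2]) & ys <= max(p[, 2]))
    if (!length(cand)) next
    inside <- pracma::inpolygon(xs[cand], ys[cand], p[, 1], p[, 2],
                                boundary = TRUE)
    hit <- cand[inside]
    if (any(lab[hit] != 0L)) {
      overlap <- TRUE
      hit <- hit[lab[hit] == 0L]
    }
    lab[hit] <- k
  }
  if (overlap)
    warning("overlapping zones: cells assigned to the first zone in list order")
  attr(lab, "zone_ids") <- zone_ids(zones)
  lab
}

#' Build rectangular pseudo-city zones tiling a grid
#'
#' Lays `nx` by `ny` rectangular zones over the template extent, optionally
#' separated by a gap; a convenient stand-in for urban boundaries in
#' synthetic studies.
#'
#' @param template a [gx_grid].
#' @param nx,ny number of zones along x and y.
#' @param gap gap between rectangles in metres.
#' @param hemisphere hemisphere attribute given to every zone.
#' @return a [zone_set] with ids `city_001`, `city_002`, ...
#' @export
rect_zones <- function(template, nx, ny, gap = 0, hemisphere = "N") {
  nr <- nrow(template$values); nc <- ncol(template$values)
  cs <- template$cell_size
  w <- nc * cs / nx; h <- nr * cs / ny
  x0 <- template$origin[1]; y0 <- template$origin[2]
  zones <- list(); k <- 0L
  for (j in seq_len(ny)) {
    for (i in seq_len(nx)) {
      k <- k + 1L
      xa <- x0 + (i - 1) * w + gap / 2; xb <- x0 + i * w - gap / 2
      ya <- y0 - (j - 1) * h - gap / 2; yb <- y0 - j * h + gap / 2
      zones[[k]] <- list(zone_id = sprintf("city_%03d", k),
                         polygon = rbind(c(xa, yb), c(xb, yb),
                                         c(xb, ya), c(xa, ya)),
                         hemisphere = hemisphere)
    }
  }
  zone_set(zones)
}
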