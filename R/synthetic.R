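#' Parameters for a synthetic landscape
#'
#' Describes one synthetic city/landscape: grid shape and resolution, the
#' spatial autocorrelation scale of the greenspace field, the target mean
#' greenspace fraction, and the size, clustering and greenspace coupling of
#' the population surface.
#'
#' @param shape integer length-2, (rows, cols).
#' @param cell_size cell edge in metres.
#' @param correlation_length autocorrelation scale of the underlying Gaussian
#'   field, metres (>= `cell_size`).
#' @param target_coverage mean greenspace fraction over valid cells, in
#'   `[0, 1]`.
#' @param pop_total total population (non-negative integer).
#' @param pop_clustering lognormal sigma of the population intensity field
#'   (0 = uniform).
#' @param pop_green_corr in `[-1, 1]`; sign and strength of the coupling
#'   between population log-intensity and greenspace fraction.
#' @param seed integer seed; all generators are seed-deterministic.
#' @return a list of class `landscape_params`.
#' @export
landscape_params <- function(shape = c(128, 128), cell_size = 100,
                             correlation_length = 500,
                             target_coverage = 0.35,
                             pop_total = 100000L, pop_clustering = 1,
                             pop_green_corr = 0, seed = 1L) {
  stopifnot(length(shape) == 2L, all(shape >= 1), cell_size > 0,
            correlation_length > 0,
            target_coverage >= 0, target_coverage <= 1,
            pop_total >= 0, pop_clustering >= 0,
            pop_green_corr >= -1, pop_green_corr <= 1)
  if (abs(pop_total - round(pop_total)) > 0)
    stop("'pop_total' must be an integer count of persons")
  structure(list(shape = as.integer(shape), cell_size = cell_size,
                 correlation_length = correlation_length,
                 target_coverage = target_coverage,
                 pop_total = as.numeric(round(pop_total)),
                 pop_clustering = pop_clustering,
                 pop_green_corr = pop_green_corr, seed = as.integer(seed)),
            class = "landscape_params")
}

#' Parameters for a seasonal phenology stack
#'
#' @param deciduous_fraction fraction of green cells that are deciduous,
#'   in `[0, 1]`.
#' @param winter_retention fraction of a deciduous cell's summer greenness
#'   kept in winter, `[0, 1]`.
#' @param shoulder_retention spring/autumn level between summer and winter,
#'   `[0, 1]`.
#' @param seed integer seed for the deciduous membership draw.
#' @return a list of class `seasonal_params`.
#' @export
seasonal_params <- function(deciduous_fraction = 0.5, winter_retention = 0.2,
                            shoulder_retention = 0.6, seed = 1L) {
  stopifnot(deciduous_fraction >= 0, deciduous_fraction <= 1,
            winter_retention >= 0, winter_retention <= 1,
            shoulder_retention >= 0, shoulder_retention <= 1)
  structure(list(deciduous_fraction = deciduous_fraction,
                 winter_retention = winter_retention,
                 shoulder_retention = shoulder_retention,
                 seed = as.integer(seed)),
            class = "seasonal_params")
}

#' Spatially autocorrelated Gaussian random field
#'
#' Synthesizes a zero-mean, unit-variance (sample-standardized) field whose
#' spatial autocorrelation follows a Gaussian correlogram
#' \eqn{\rho(h) = \exp(-h^2 / (2 L^2))} with scale `correlation_length`,
#' by spectral (FFT) filtering of white noise. Identical seeds give
#' identical fields.
#'
#' @param shape integer length-2, (rows, cols).
#' @param correlation_length scale L in metres; must be >= `cell_size`.
#' @param cell_size cell edge in metres.
#' @param seed integer seed.
#' @return a numeric matrix with sample mean 0 and sample sd 1.
#' @export
gen_gaussian_field <- function(shape, correlation_length, cell_size,
                               seed = 1L) {
  if (correlation_length < cell_size)
    stop("'correlation_length' must be >= 'cell_size'")
  nr <- shape[1]; nc <- shape[2]
  # correlation kernel over torus distances, spectrum via 2-D FFT
  di <- pmin(0:(nr - 1), nr - 0:(nr - 1)) * cell_size
  dj <- pmin(0:(nc - 1), nc - 0:(nc - 1)) * cell_size
  h2 <- outer(di^2, dj^2, `+`)
  corr <- exp(-h2 / (2 * correlation_length^2))
  spec <- Re(stats::fft(corr))
  spec[spec < 0] <- 0
  w <- withr::with_seed(seed, matrix(stats::rnorm(nr * nc), nr, nc))
  f <- Re(stats::fft(stats::fft(w) * sqrt(spec), inverse = TRUE)) / (nr * nc)
  if (length(f) > 1L && stats::sd(f) > 0) f <- (f - mean(f)) / stats::sd(f)
  else f <- f - mean(f)
  f
}

#' Generate a fractional greenspace grid
#'
#' Rank-transforms a spatially autocorrelated Gaussian field to a
#' Beta-like marginal on `[0, 1]` (uniform scores raised to a power), then
#' solves for the power so the grid mean matches `target_coverage` exactly
#' (a monotone, order-preserving adjustment).
#'
#' @param params a [landscape_params].
#' @return a greenspace-role [gx_grid] whose mean over valid cells equals
#'   `target_coverage` to within `1 / (2 * n_cells)`.
#' @export
gen_greenspace <- function(params) {
  stopifnot(inherits(params, "landscape_params"))
  nr <- params$shape[1]; nc <- params$shape[2]; n <- nr * nc
  tc <- params$target_coverage
  if (tc == 0) {
    m <- matrix(0, nr, nc)
  } else if (tc == 1) {
    m <- matrix(1, nr, nc)
  } else {
    f <- gen_gaussian_field(params$shape, params$correlation_length,
                            params$cell_size, seed = params$seed)
    u <- matrix(rank(f, ties.method = "first") / (n + 1), nr, nc)
    # mean(u^a) is continuous and strictly decreasing in a; bracket and solve
    target_fun <- function(loga) mean(u^exp(loga)) - tc
    root <- stats::uniroot(target_fun, interval = c(-40, 40),
                           tol = .Machine$double.eps^0.75)
    m <- u^exp(root$root)
  }
  gx_grid(m, cell_size = params$cell_size, role = "greenspace")
}

#' Generate a clustered population grid
#'
#' Builds a lognormal population intensity surface whose log couples to the
#' greenspace fraction with the sign and strength of `pop_green_corr`
#' (a mixture of the standardized greenspace field and an independent
#' autocorrelated field), scales it to `pop_total`, and integerizes by the
#' largest-remainder rule so the total is conserved exactly.
#'
#' @param params a [landscape_params].
#' @param greenspace a greenspace-role [gx_grid] with the shape requested in
#'   `params`.
#' @return a population-role [gx_grid] of integer counts summing exactly to
#'   `pop_total`.
#' @export
gen_population <- function(params, greenspace) {
  stopifnot(inherits(params, "landscape_params"),
            inherits(greenspace, "gx_grid"))
  if (!identical(dim(greenspace$values), params$shape))
    stop("greenspace grid does not match the requested shape")
  if (params$pop_total < 0) stop("'pop_total' must be >= 0")
  nr <- params$shape[1]; nc <- params$shape[2]
  g <- greenspace$values
  rho <- params$pop_green_corr
  noise <- gen_gaussian_field(params$shape, params$correlation_length,
                              params$cell_size, seed = params$seed + 1L)
  gs <- if (stats::sd(g) > 0) (g - mean(g)) / stats::sd(g) else g * 0
  latent <- rho * gs + sqrt(1 - rho^2) * noise
  intensity <- exp(params$pop_clustering * latent)
  lambda <- params$pop_total * intensity / sum(intensity)
  counts <- largest_remainder(as.vector(lambda), params$pop_total)
  gx_grid(matrix(counts, nr, nc), cell_size = params$cell_size,
          origin = greenspace$origin, role = "population",
          crs = greenspace$crs)
}

# Integerize non-negative quotas so they sum exactly to 'total':
# floors first, then +1 to the largest fractional remainders (ties by index).
largest_remainder <- function(quota, total) {
  base <- floor(quota)
  rem <- round(total - sum(base))
  if (rem > 0) {
    idx <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[idx] <- base[idx] + 1
  }
  base
}

#' Generate a four-season greenspace stack
#'
#' Takes `base` as the summer (leaf-on) state. A seeded per-cell draw marks
#' a `deciduous_fraction` subset of green cells as deciduous; those cells are
#' scaled by `winter_retention` in winter and `shoulder_retention` in
#' spring/autumn, while evergreen cells keep their summer value year-round.
#'
#' @param base greenspace-role [gx_grid], the summer state.
#' @param params a [seasonal_params].
#' @return named list of four greenspace grids: `spring`, `summer`,
#'   `autumn`, `winter`.
#' @export
gen_seasonal_stack <- function(base, params) {
  stopifnot(inherits(base, "gx_grid"), inherits(params, "seasonal_params"))
  v <- base$values
  green <- !is.na(v) & v > 0
  dec <- matrix(FALSE, nrow(v), ncol(v))
  dec[green] <- withr::with_seed(
    params$seed, stats::runif(sum(green)) < params$deciduous_fraction)
  season_grid <- function(retention) {
    s <- v
    s[dec] <- v[dec] * retention
    gx_grid(s, cell_size = base$cell_size, origin = base$origin,
            role = "greenspace", crs = base$crs)
  }
  list(spring = season_grid(params$shoulder_retention),
       summer = season_grid(1),
       autumn = season_grid(params$shoulder_retention),
       winter = season_grid(params$winter_retention))
}

#' Default distributions for the 16 city-level driver covariates
#'
#' Means and standard deviations used by [gen_city_collection] for the five
#' covariate categories: geographic (lat, lon), topographic (elevation,
#' slope), climate (prcp, temp, vpd), socioeconomic (ntl, pop_density,
#' road_length) and landscape (gcr, mean_patch_size, largest_patch_size,
#' pa_ratio, shape_index, ed).
#'
#' @return data.frame with columns `covariate`, `mean`, `sd`, `min`, `max`.
#' @export
covariate_distributions <- function() {
  data.frame(
    covariate = c("lat", "lon", "elevation", "slope", "prcp", "temp", "vpd",
                  "ntl", "pop_density", "road_length", "gcr",
                  "mean_patch_size", "largest_patch_size", "pa_ratio",
                  "shape_index", "ed"),
    mean = c(35, 0, 300, 5, 80, 15, 0.9, 20, 3000, 5, 0.35,
             5e4, 5e5, 0.05, 1.5, 120),
    sd = c(15, 80, 250, 4, 40, 8, 0.4, 15, 2500, 3, 0.18,
           3e4, 4e5, 0.02, 0.3, 60),
    min = c(-60, -180, 0, 0, 0, -20, 0.05, 0, 10, 0.1, 0.01,
            1e3, 1e4, 0.005, 1, 5),
    max = c(70, 180, 4000, 30, 400, 35, 3, 80, 20000, 20, 0.95,
            5e5, 5e6, 0.2, 3, 500),
    stringsAsFactors = FALSE)
}

#' Parameters for a synthetic multi-city driver table
#'
#' @param n_cities number of cities (>= 3).
#' @param planted_coefficients named numeric vector of effects of the
#'   0-1-rescaled covariates on the Gini response; defaults to a
#'   landscape-only model (negative provision and configuration effects).
#' @param intercept response intercept.
#' @param noise_sd Gaussian noise sd added to the response (>= 0).
#' @param distributions covariate distribution table, see
#'   [covariate_distributions].
#' @param seed integer seed.
#' @return a list of class `city_collection_params`.
#' @export
city_collection_params <- function(n_cities = 1028L,
                                   planted_coefficients =
                                     c(gcr = -0.115, ed = -0.047),
                                   intercept = 0.355,
                                   noise_sd = 0.05,
                                   distributions = covariate_distributions(),
                                   seed = 1L) {
  stopifnot(n_cities >= 3, noise_sd >= 0)
  if (!all(names(planted_coefficients) %in% distributions$covariate))
    stop("planted coefficients name unknown covariates")
  structure(list(n_cities = as.integer(n_cities),
                 planted_coefficients = planted_coefficients,
                 intercept = intercept, noise_sd = noise_sd,
                 distributions = distributions, seed = as.integer(seed)),
            class = "city_collection_params")
}

#' Generate a multi-city driver table with known coefficients
#'
#' Draws the 16 covariates independently from truncated normal
#' distributions, min-max rescales them to `[0, 1]`, and generates the Gini
#' response as the planted linear combination of the rescaled covariates
#' plus Gaussian noise, clipped to `[0, 1]`. The generative coefficients are
#' returned alongside so recovery can be tested.
#'
#' @param params a [city_collection_params].
#' @return list with `table` (data.frame: `city_id`, `gini`, 16 covariates on
#'   their raw scales), `rescaled` (same with covariates min-max rescaled),
#'   `coefficients` (the planted vector, zero-filled over all covariates),
#'   `intercept`, and `n_clipped` (rows whose response hit the `[0, 1]` clip).
#' @export
gen_city_collection <- function(params) {
  stopifnot(inherits(params, "city_collection_params"))
  d <- params$distributions
  n <- params$n_cities
  withr::with_seed(params$seed, {
    X <- sapply(seq_len(nrow(d)), function(j) {
      pmin(pmax(stats::rnorm(n, d$mean[j], d$sd[j]), d$min[j]), d$max[j])
    })
    noise <- stats::rnorm(n, 0, params$noise_sd)
  })
  colnames(X) <- d$covariate
  Xs <- apply(X, 2L, function(x) {
    r <- range(x)
    if (diff(r) == 0) rep(0, length(x)) else (x - r[1]) / diff(r)
  })
  beta <- stats::setNames(numeric(nrow(d)), d$covariate)
  beta[names(params$planted_coefficients)] <- params$planted_coefficients
  y_raw <- params$intercept + as.vector(Xs %*% beta) + noise
  y <- pmin(pmax(y_raw, 0), 1)
  tab <- data.frame(city_id = sprintf("city_%04d", seq_len(n)),
                    gini = y, X, stringsAsFactors = FALSE)
  tab_rs <- data.frame(city_id = tab$city_id, gini = y, Xs,
                       stringsAsFactors = FALSE)
  list(table = tab, rescaled = tab_rs, coefficients = beta,
       intercept = params$intercept, n_clipped = sum(y != y_raw))
}
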