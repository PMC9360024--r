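test_that("aggregate_fraction computes block means with nodata handling", {
  ones <- fgrid(matrix(1, 10, 10), cell_size = 10)
  a <- aggregate_fraction(ones, 10)
  expect_equal(a$values, matrix(1, 1, 1))
  expect_equal(a$cell_size, 100)
  # 37 of 100 ones -> 0.37
  m <- matrix(0, 10, 10); m[seq_len(37)] <- 1
  expect_equal(aggregate_fraction(fgrid(m, 10), 10)$values[1, 1], 0.37)
  # non-divisible dimensions are an error, not implicit padding
  expect_error(aggregate_fraction(fgrid(matrix(0, 15, 15), 10), 10),
               "divisible")
  # nodata: coarse cell nodata only when the whole block is nodata
  m2 <- matrix(c(1, NA, NA, NA), 2, 2)
  m3 <- rbind(cbind(m2, matrix(NA, 2, 2)), matrix(0, 2, 4))
  a3 <- aggregate_fraction(fgrid(m3, 10), 2)
  expect_equal(a3$values[1, 1], 1)       # one valid cell of four
  expect_true(is.na(a3$values[1, 2]))    # fully-nodata block
  expect_equal(a3$values[2, ], c(0, 0))
  # non-binary input rejected
  expect_error(aggregate_fraction(fgrid(matrix(0.5, 2, 2), 10), 2),
               "binary")
})

test_that("aggregation preserves zonal coverage", {
  set.seed(11)
  fine <- fgrid(matrix(rbinom(80 * 80, 1, 0.4), 80, 80), cell_size = 10)
  coarse <- aggregate_fraction(fine, 10)
  all_of <- function(g) matrix(TRUE, nrow(g$values), ncol(g$values))
  expect_equal(greenspace_coverage(coarse, all_of(coarse)),
               greenspace_coverage(fine, all_of(fine)), tolerance = 1e-12)
})

test_that("focal_fraction matches enumeration on the 5x5 cross case and
           small radii are the identity", {
  m <- matrix(0, 5, 5); m[3, 3] <- 1
  f <- focal_fraction(fgrid(m, 100), 100)
  # kernel at 100 m = center + 4 orthogonal neighbours (inclusive boundary)
  expect_equal(f$values[3, 3], 0.2)
  expect_equal(f$values[3, 2], 0.2)
  expect_equal(f$values[2, 2], 0)    # diagonal at sqrt(2)*100 > 100
  g <- fgrid(matrix(runif(25), 5, 5), 100)
  expect_equal(focal_fraction(g, 99)$values, g$values)
  expect_equal(focal_fraction(g, 0)$values, g$values)
})

test_that("constant fields are fixed points of focal_fraction", {
  for (r in c(0, 150, 500, 1200)) {
    g <- fgrid(matrix(0.42, 20, 20), 100)
    expect_equal(focal_fraction(g, r)$values, g$values, tolerance = 1e-12)
  }
})

test_that("focal_fraction equals the brute-force circular kernel", {
  set.seed(21)
  m <- matrix(runif(40 * 40), 40, 40)
  m[sample(length(m), 30)] <- NA
  g <- fgrid(m, 100)
  for (r in c(100, 250, 520)) {
    expect_equal(focal_fraction(g, r)$values, focal_brute(m, 100, r),
                 tolerance = 1e-10)
  }
})

test_that("greenspace_coverage and population_weighted_exposure match hand
           evaluations", {
  g <- fgrid(matrix(c(0, 0.5, 0.5, 1), 2, 2), 100)
  all_mask <- matrix(TRUE, 2, 2)
  expect_equal(greenspace_coverage(g, all_mask), 0.5)
  expect_equal(greenspace_coverage(fgrid(matrix(1, 3, 3), 100),
                                   matrix(TRUE, 3, 3)), 1)
  expect_equal(greenspace_coverage(fgrid(matrix(0, 3, 3), 100),
                                   matrix(TRUE, 3, 3)), 0)
  expect_error(greenspace_coverage(g, matrix(FALSE, 2, 2)), "empty zone")
  # P = [1, 3], G = [0.2, 0.6] -> GE = (0.2 + 1.8)/4 = 0.5
  pop <- gx_grid(matrix(c(1, 3), 1, 2), 100, role = "population")
  gd <- fgrid(matrix(c(0.2, 0.6), 1, 2), 100)
  expect_equal(population_weighted_exposure(pop, gd, matrix(TRUE, 1, 2)),
               0.5)
  # all population in one cell -> GE is that cell's exposure
  pop1 <- gx_grid(matrix(c(0, 7), 1, 2), 100, role = "population")
  expect_equal(population_weighted_exposure(pop1, gd, matrix(TRUE, 1, 2)),
               0.6)
  # zero population is an error, not a silent 0
  pop0 <- gx_grid(matrix(0, 1, 2), 100, role = "population")
  expect_error(population_weighted_exposure(pop0, gd, matrix(TRUE, 1, 2)),
               "no population")
})

test_that("uniform population reduces GE to the unweighted mean of G^d", {
  set.seed(31)
  g <- gen_greenspace(landscape_params(shape = c(32, 32), seed = 12))
  gd <- focal_fraction(g, 500)
  pop <- gx_grid(matrix(5, 32, 32), 100, role = "population")
  mask <- matrix(TRUE, 32, 32)
  expect_equal(population_weighted_exposure(pop, gd, mask),
               mean(gd$values), tolerance = 1e-12)
})

test_that("GE^d lies between the zone's min and max buffered fraction", {
  for (seed in 1:5) {
    lp <- landscape_params(shape = c(32, 32), pop_total = 5000L,
                           pop_green_corr = runif(1, -0.9, 0.9),
                           seed = seed)
    g <- gen_greenspace(lp)
    p <- gen_population(lp, g)
    for (r in c(200, 500)) {
      gd <- focal_fraction(g, r)
      mask <- matrix(TRUE, 32, 32)
      ge <- population_weighted_exposure(p, gd, mask)
      expect_gte(ge, min(gd$values))
      expect_lte(ge, max(gd$values))
    }
  }
})

test_that("exposure_report composes the per-zone operations and flags
           failing zones instead of dropping them", {
  lp <- landscape_params(shape = c(40, 40), pop_total = 8000L, seed = 14)
  g <- gen_greenspace(lp)
  p <- gen_population(lp, g)
  zones <- rect_zones(g, 2, 2)
  rep4 <- exposure_report(g, p, zones, radii = c(100, 500, 1000, 1500))
  df <- as.data.frame(rep4)
  expect_identical(nrow(df), 4L)
  ge_cols <- paste0("GE_", c(100, 500, 1000, 1500))
  expect_true(all(ge_cols %in% names(df)))
  expect_true(all(df[ge_cols] >= 0 & df[ge_cols] <= 1))
  # composition: report values equal the standalone operations
  lab <- rasterize_zones(zones, g)
  gd <- focal_fraction(g, 100)
  expect_equal(df$GC[1], greenspace_coverage(g, lab == 1L))
  expect_equal(df$GE_100[1],
               population_weighted_exposure(p, gd, lab == 1L))
  # a zone with zero population is flagged, not dropped
  p0 <- p
  p0$values[lab == 2L] <- 0
  rep0 <- exposure_report(g, p0, zones, radii = 500)
  df0 <- as.data.frame(rep0)
  expect_match(df0$flag[2], "no population")
  expect_true(all(is.na(df0$flag[-2])))
})

test_that("buffer_sensitivity reports mean |dGE| in percentage points", {
  lp <- landscape_params(shape = c(40, 40), pop_total = 8000L, seed = 15)
  g <- gen_greenspace(lp)
  p <- gen_population(lp, g)
  r <- exposure_report(g, p, rect_zones(g, 2, 2), radii = c(500, 1500))
  expect_equal(buffer_sensitivity(r, 500, 500), 0)
  manual <- mean(vapply(r, function(z)
    abs(z$GE_by_radius[["500"]] - z$GE_by_radius[["1500"]]), numeric(1)))
  expect_equal(buffer_sensitivity(r, 500, 1500), manual * 100)
  expect_error(buffer_sensitivity(r, 500, 700), "missing")
  # constant greenspace -> zero discrepancy for any radius pair
  gc <- fgrid(matrix(0.3, 40, 40), 100)
  rc <- exposure_report(gc, p, rect_zones(gc, 2, 2), radii = c(500, 1500))
  expect_equal(buffer_sensitivity(rc, 500, 1500), 0, tolerance = 1e-10)
})
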