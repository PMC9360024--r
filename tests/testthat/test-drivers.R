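make_table <- function(n = 200, seed = 1, planted = c(gcr = -0.3,
                                                      ed = -0.15),
                       noise_sd = 0.05) {
  gen_city_collection(city_collection_params(
    n_cities = n, planted_coefficients = planted, noise_sd = noise_sd,
    seed = seed))
}

test_that("rescale_01 maps covariates to [0, 1] and flags constants", {
  tab <- data.frame(gini = c(0.2, 0.4, 0.6),
                    lat = c(2, 4, 6), gcr = c(0, 0.5, 1),
                    ed = c(7, 7, 7))
  rs <- rescale_01(tab, covariates = c("lat", "gcr", "ed"))
  expect_equal(rs$lat, c(0, 0.5, 1))
  expect_equal(rs$gcr, c(0, 0.5, 1))          # already [0,1]: unchanged
  expect_equal(rs$ed, c(0, 0, 0))             # constant: mapped to 0
  expect_identical(attr(rs, "constant_columns"), "ed")
  expect_equal(rs$gini, tab$gini)             # response untouched
})

test_that("partial correlation reduces to Pearson with no controls and
           matches the residual-regression oracle", {
  set.seed(111)
  n <- 120
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("x", 1:4)))
  y <- 0.5 * X[, 1] - 0.3 * X[, 2] + rnorm(n, 0, 0.5)
  # empty control set: pcor == Pearson r
  pc1 <- greenexposure:::pcor_precision(y, X[, 1, drop = FALSE])
  expect_equal(unname(pc1), cor(y, X[, 1]), tolerance = 1e-12)
  # against the residual-regression oracle, all four covariates
  pc <- greenexposure:::pcor_precision(y, X)
  for (j in 1:4)
    expect_equal(unname(pc[j]),
                 pcor_residual(y, X[, j], X[, -j, drop = FALSE]),
                 tolerance = 1e-10)
})

test_that("screening selects exactly the planted drivers on a large
           collection and excludes constant columns", {
  cc <- make_table(n = 1000, seed = 7)
  rs <- rescale_01(cc$table)
  scr <- screen_variables(rs)
  expect_setequal(scr$selected, c("gcr", "ed"))
  expect_identical(nrow(scr$report), 16L)
  # a constant column is excluded, not crashed on
  tab2 <- cc$table
  tab2$slope <- 1
  scr2 <- screen_variables(rescale_01(tab2))
  expect_true(scr2$report$excluded[scr2$report$covariate == "slope"])
  expect_setequal(scr2$selected, c("gcr", "ed"))
  expect_error(screen_variables(rescale_01(cc$table[1:10, ])), ">= 20")
})

test_that("ols_nested recovers noiseless responses exactly and matches the
           normal-equations oracle", {
  cc0 <- gen_city_collection(city_collection_params(
    n_cities = 150, noise_sd = 0,
    planted_coefficients = c(lat = 0.05, prcp = -0.03, vpd = 0.08,
                             gcr = -0.115, ed = -0.047), seed = 13))
  m <- suppressWarnings(ols_nested(cc0$rescaled))  # exact-fit lm warning
  cf <- m$model4$coefficients
  expect_equal(cf$estimate[cf$term == "gcr"], -0.115, tolerance = 1e-8)
  expect_equal(cf$estimate[cf$term == "ed"], -0.047, tolerance = 1e-8)
  expect_equal(cf$estimate[cf$term == "(Intercept)"], 0.355,
               tolerance = 1e-8)
  expect_equal(m$model4$adj_r_squared, 1, tolerance = 1e-10)
  # normal-equations oracle on a noisy table
  cc <- make_table(n = 300, seed = 17)
  rs <- rescale_01(cc$table)
  m2 <- ols_nested(rs)
  X <- cbind(1, as.matrix(rs[c("lat", "prcp", "vpd", "gcr", "ed")]))
  beta <- solve(t(X) %*% X, t(X) %*% rs$gini)
  expect_equal(m2$model4$coefficients$estimate, as.vector(beta),
               tolerance = 1e-8)
  # nesting monotonicity: adding covariates never lowers raw R^2
  expect_gte(m2$model4$r_squared, m2$model3$r_squared)
  expect_gte(m2$model4$r_squared, m2$model2$r_squared)
  expect_gte(m2$model4$r_squared, m2$model1$r_squared)
  # adjusted R^2 follows its definition
  n <- m2$model3$n; p <- 2
  expect_equal(m2$model3$adj_r_squared,
               1 - (1 - m2$model3$r_squared) * (n - 1) / (n - p - 1),
               tolerance = 1e-12)
  # rank deficiency is a named error
  rs$dup <- rs$gcr
  expect_error(ols_nested(rs, list(m = c("gcr", "dup"))), "collinear")
})

test_that("vif matches its definition and flags perfect collinearity", {
  set.seed(121)
  n <- 200
  tab <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  tab$d <- 0.8 * tab$a + 0.6 * tab$b + rnorm(n, 0, 0.3)
  v <- vif(tab, c("a", "b", "c", "d"))
  # oracle: independent per-column regressions
  for (cv in names(v)) {
    r2 <- summary(lm(reformulate(setdiff(c("a", "b", "c", "d"), cv),
                                 response = cv), data = tab))$r.squared
    expect_equal(unname(v[cv]), 1 / (1 - r2), tolerance = 1e-8)
  }
  expect_gt(v["d"], v["c"])
  # near-orthogonal predictors: VIF close to 1
  expect_lt(max(vif(tab, c("a", "b", "c"))), 1.1)
  # duplicated predictor: infinity flag
  tab$a2 <- tab$a
  expect_identical(unname(suppressWarnings(vif(tab, c("a", "a2")))["a"]),
                   Inf)
})

test_that("vif agrees with the standard car implementation", {
  skip_if_not_installed("car")
  cc <- make_table(n = 400, seed = 19)
  rs <- rescale_01(cc$table)
  covs <- c("lat", "prcp", "vpd", "gcr", "ed")
  ours <- vif(rs, covs)
  fit <- lm(reformulate(covs, response = "gini"), data = rs)
  expect_equal(unname(ours), unname(car::vif(fit)[covs]),
               tolerance = 1e-10)
})

test_that("variance partition fractions sum to one and recover designed
           structures", {
  set.seed(131)
  n <- 2000
  # orthogonal drivers: joint ~ 0
  a <- rnorm(n); b <- rnorm(n)
  tab <- data.frame(gini = 0.4 + 0.1 * a + 0.1 * b + rnorm(n, 0, 0.1),
                    gcr = a, ed = b)
  vp <- variance_partition(tab)
  expect_equal(vp$unique_a + vp$unique_b + vp$joint + vp$residual, 1,
               tolerance = 1e-10)
  expect_lt(abs(vp$joint), 0.05)
  expect_gt(vp$unique_a, 0.1)
  # shared latent factor: joint dominates
  z <- rnorm(n)
  tab2 <- data.frame(gcr = z + rnorm(n, 0, 0.4),
                     ed = z + rnorm(n, 0, 0.4))
  tab2$gini <- 0.4 + 0.15 * z + rnorm(n, 0, 0.05)
  vp2 <- variance_partition(tab2)
  expect_gt(vp2$joint, 0.3)
  expect_equal(vp2$unique_a + vp2$unique_b + vp2$joint + vp2$residual, 1,
               tolerance = 1e-10)
  # single-driver limit: response depends on A only, noiseless. The
  # adjusted R^2 of the pure-noise fit is slightly negative, so the
  # fractions sit within O(1/n) of the ideal 1/0/0, not exactly on it.
  tab3 <- data.frame(gcr = a, ed = b, gini = 0.5 - 0.1 * a)
  vp3 <- suppressWarnings(variance_partition(tab3))
  expect_equal(vp3$unique_a, 1, tolerance = 1e-2)
  expect_equal(vp3$unique_b, 0, tolerance = 1e-2)
  expect_equal(vp3$residual, 0, tolerance = 1e-6)
  expect_equal(vp3$unique_a + vp3$unique_b + vp3$joint + vp3$residual, 1,
               tolerance = 1e-10)
})

test_that("variance partition agrees with vegan's varpart", {
  skip_if_not_installed("vegan")
  set.seed(141)
  n <- 300
  z <- rnorm(n)
  tab <- data.frame(gcr = z + rnorm(n, 0, 0.5), ed = z + rnorm(n, 0, 0.5))
  tab$gini <- 0.4 + 0.1 * z + rnorm(n, 0, 0.08)
  vp <- variance_partition(tab)
  vv <- vegan::varpart(tab$gini, ~gcr, ~ed, data = tab)$part$indfract
  expect_equal(vp$unique_a, vv["[a] = X1|X2", "Adj.R.squared"],
               tolerance = 1e-8)
  expect_equal(vp$unique_b, vv["[b] = X2|X1", "Adj.R.squared"],
               tolerance = 1e-8)
  expect_equal(vp$joint, vv["[c]", "Adj.R.squared"], tolerance = 1e-8)
  expect_equal(vp$residual, vv["[d] = Residuals", "Adj.R.squared"],
               tolerance = 1e-8)
})

test_that("screening and model fitting are deterministic given the table", {
  cc <- make_table(n = 250, seed = 23)
  rs <- rescale_01(cc$table)
  s1 <- screen_variables(rs); s2 <- screen_variables(rs)
  expect_identical(s1, s2)
  m1 <- ols_nested(rs); m2 <- ols_nested(rs)
  expect_identical(m1$model4$coefficients, m2$model4$coefficients)
})
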