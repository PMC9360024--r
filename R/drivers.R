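driver_covariates <- function() covariate_distributions()$covariate

#' Min-max rescale driver covariates to \[0, 1\]
#'
#' Each covariate column becomes `(x - min) / (max - min)`; the Gini
#' response is left unscaled. Constant columns cannot be rescaled: they are
#' mapped to 0 and flagged so screening can exclude them.
#'
#' @param table data.frame with a `gini` response column and covariate
#'   columns (see [covariate_distributions] for the canonical 16).
#' @param covariates character vector of covariate column names; defaults to
#'   every canonical covariate present in `table`.
#' @return the table with rescaled covariates; attribute
#'   `constant_columns` names any flagged columns.
#' @export
rescale_01 <- function(table, covariates = NULL) {
  if (is.null(covariates))
    covariates <- intersect(driver_covariates(), names(table))
  if (!length(covariates)) stop("no covariate columns found")
  constant <- character(0)
  for (cv in covariates) {
    r <- range(table[[cv]])
    if (diff(r) == 0) {
      constant <- c(constant, cv)
      table[[cv]] <- rep(0, nrow(table))
    } else {
      table[[cv]] <- (table[[cv]] - r[1]) / diff(r)
    }
  }
  attr(table, "constant_columns") <- constant
  attr(table, "covariates") <- covariates
  table
}

# partial correlation of y with each column of X controlling the others,
# via the precision (inverse correlation) matrix
pcor_precision <- function(y, X) {
  M <- cbind(y = y, X)
  R <- stats::cor(M)
  P <- tryCatch(solve(R), error = function(e) NULL)
  if (is.null(P)) return(NULL)
  d <- sqrt(diag(P))
  pc <- -P[1, -1] / (d[1] * d[-1])
  pc
}

#' Screen driver covariates by correlation rules
#'
#' For every covariate: Pearson correlation with the response (two-sided
#' p-value) and the partial correlation controlling for all other
#' covariates. A covariate is selected when it passes all three rules:
#' p-value below `alpha`, `|r|` above `r_min`, and `|partial r|` above
#' `pc_min` (defaults: 0.001, 0.1, 0.1). Constant or collinear covariates
#' are flagged and excluded.
#'
#' @param table a rescaled driver table (see [rescale_01]) with a `gini`
#'   response and at least 20 rows.
#' @param response response column name.
#' @param alpha significance level for the Pearson p-value.
#' @param r_min,pc_min absolute correlation and partial-correlation
#'   thresholds.
#' @return list with `selected` (character vector) and `report`
#'   (data.frame: covariate, r, p, pcor, p_pcor, excluded, selected).
#' @export
screen_variables <- function(table, response = "gini", alpha = 0.001,
                             r_min = 0.1, pc_min = 0.1) {
  covs <- attr(table, "covariates")
  if (is.null(covs)) covs <- intersect(driver_covariates(), names(table))
  if (nrow(table) < 20L)
    stop("screening needs >= 20 rows; correlation estimates are unstable")
  constant <- attr(table, "constant_columns")
  if (is.null(constant))
    constant <- covs[vapply(covs, function(cv) diff(range(table[[cv]])) == 0,
                            logical(1))]
  usable <- setdiff(covs, constant)
  y <- table[[response]]
  n <- nrow(table)
  X <- as.matrix(table[usable])
  pc <- pcor_precision(y, X)
  rows <- lapply(covs, function(cv) {
    if (cv %in% constant || is.null(pc) || is.na(pc[cv]))
      return(data.frame(covariate = cv, r = NA_real_, p = NA_real_,
                        pcor = NA_real_, p_pcor = NA_real_, excluded = TRUE,
                        selected = FALSE, stringsAsFactors = FALSE))
    ct <- stats::cor.test(y, table[[cv]])
    k <- length(usable) - 1L            # number of controls
    pcv <- pc[cv]
    tstat <- pcv * sqrt((n - 2 - k) / max(1 - pcv^2, .Machine$double.eps))
    p_pc <- 2 * stats::pt(-abs(tstat), df = n - 2 - k)
    sel <- ct$p.value < alpha && abs(ct$estimate) > r_min && abs(pcv) > pc_min
    data.frame(covariate = cv, r = unname(ct$estimate), p = ct$p.value,
               pcor = unname(pcv), p_pcor = p_pc, excluded = FALSE,
               selected = sel, stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  list(selected = report$covariate[report$selected], report = report)
}

#' Nested OLS models of exposure inequality
#'
#' Fits the standard model ladder: geography alone, climate alone,
#' landscape alone, and all covariates together. Coefficients are reported
#' on the `[0, 1]`-rescaled covariate scale with the raw response, and
#' additionally as standardized (z-score of both sides) coefficients; both
#' conventions appear in the literature, so both are emitted.
#'
#' @param table a rescaled driver table with a `gini` response.
#' @param model_specs named list of covariate vectors; the default is
#'   `model1 = lat`, `model2 = prcp + vpd`, `model3 = gcr + ed`,
#'   `model4 = all five`.
#' @param response response column name.
#' @return list of class `ols_nested`, one element per model:
#'   `coefficients` (data.frame: term, estimate, std_estimate, se, t, p),
#'   `r_squared`, `adj_r_squared`, `n`, `fit` (the `lm` object).
#' @export
ols_nested <- function(table,
                       model_specs = list(
                         model1 = "lat",
                         model2 = c("prcp", "vpd"),
                         model3 = c("gcr", "ed"),
                         model4 = c("lat", "prcp", "vpd", "gcr", "ed")),
                       response = "gini") {
  out <- lapply(model_specs, function(covs) {
    miss <- setdiff(covs, names(table))
    if (length(miss)) stop("unknown covariates: ", paste(miss, collapse = ", "))
    n <- nrow(table)
    if (n <= length(covs) + 1L)
      stop("need n > p + 1 observations for ", length(covs), " covariates")
    fml <- stats::reformulate(covs, response = response)
    fit <- stats::lm(fml, data = table)
    if (any(is.na(stats::coef(fit)))) {
      bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
      stop("rank-deficient model: collinear terms ",
           paste(bad, collapse = ", "))
    }
    sm <- summary(fit)
    ct <- sm$coefficients
    sdy <- stats::sd(table[[response]])
    sdx <- c(NA_real_, vapply(covs, function(cv) stats::sd(table[[cv]]),
                              numeric(1)))
    std <- ct[, 1] * sdx / sdy
    list(coefficients = data.frame(term = rownames(ct),
                                   estimate = ct[, 1],
                                   std_estimate = unname(std),
                                   se = ct[, 2], t = ct[, 3], p = ct[, 4],
                                   row.names = NULL,
                                   stringsAsFactors = FALSE),
         r_squared = sm$r.squared,
         adj_r_squared = sm$adj.r.squared,
         n = n, fit = fit)
  })
  structure(out, class = "ols_nested")
}

#' @export
print.ols_nested <- function(x, ...) {
  for (nm in names(x)) {
    cat(sprintf("-- %s: adj R2 = %.1f%% --\n", nm,
                100 * x[[nm]]$adj_r_squared))
    print(x[[nm]]$coefficients[, c("term", "estimate", "p")], digits = 3)
  }
  invisible(x)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` comes from regressing covariate j
#' on the remaining covariates; values near 1 indicate no multicollinearity.
#' Perfectly collinear covariates get `Inf`.
#'
#' @param table a driver table.
#' @param covariates character vector of >= 2 covariate names.
#' @return named numeric vector of VIFs.
#' @export
vif <- function(table, covariates) {
  if (length(covariates) < 2L) stop("need >= 2 covariates for VIF")
  if (nrow(table) <= length(covariates) + 1L)
    stop("need n > p + 1 observations")
  vapply(covariates, function(cv) {
    fml <- stats::reformulate(setdiff(covariates, cv), response = cv)
    r2 <- summary(stats::lm(fml, data = table))$r.squared
    if (1 - r2 < 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' Variance partitioning of inequality into provision and configuration
#'
#' Partitions the variation of the Gini response explained by two disjoint
#' covariate sets — by default greenspace provision (`gcr`) and greenspace
#' configuration (`ed`) — into four fractions using adjusted R2 of the
#' three fits (A alone, B alone, A and B together): the unique effect of
#' each set, their joint effect, and the unexplained residual. The four
#' fractions sum to 1 by construction; the joint fraction can be negative
#' (a suppression pattern), which is reported as-is with a warning.
#'
#' @param table a driver table with a `gini` response.
#' @param set_a,set_b disjoint, non-empty covariate sets.
#' @param response response column name.
#' @param use_adjusted use adjusted R2 (default) or raw R2.
#' @return list of class `variance_partition`: `unique_a` (provision),
#'   `unique_b` (configuration), `joint`, `residual`, plus the three R2
#'   values.
#' @export
variance_partition <- function(table, set_a = "gcr", set_b = "ed",
                               response = "gini", use_adjusted = TRUE) {
  if (!length(set_a) || !length(set_b)) stop("both sets must be non-empty")
  if (length(intersect(set_a, set_b))) stop("covariate sets must be disjoint")
  r2_of <- function(covs) {
    fit <- stats::lm(stats::reformulate(covs, response = response),
                     data = table)
    if (any(is.na(stats::coef(fit))))
      stop("rank-deficient fit for {", paste(covs, collapse = ", "), "}")
    sm <- summary(fit)
    if (use_adjusted) sm$adj.r.squared else sm$r.squared
  }
  r2_a <- r2_of(set_a); r2_b <- r2_of(set_b); r2_ab <- r2_of(c(set_a, set_b))
  joint <- r2_a + r2_b - r2_ab
  if (joint < 0)
    warning("negative joint fraction (", signif(joint, 3),
            "): suppression between the two sets")
  structure(list(unique_a = r2_ab - r2_b,
                 unique_b = r2_ab - r2_a,
                 joint = joint,
                 residual = 1 - r2_ab,
                 r2_a = r2_a, r2_b = r2_b, r2_ab = r2_ab,
                 set_a = set_a, set_b = set_b),
            class = "variance_partition")
}

#' @export
print.variance_partition <- function(x, ...) {
  cat(sprintf(paste0("<variance_partition>\n",
                     "  unique %s: %.2f%%\n  unique %s: %.2f%%\n",
                     "  joint: %.2f%%\n  residual: %.2f%%\n"),
              paste(x$set_a, collapse = "+"), 100 * x$unique_a,
              paste(x$set_b, collapse = "+"), 100 * x$unique_b,
              100 * x$joint, 100 * x$residual))
  invisible(x)
}
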