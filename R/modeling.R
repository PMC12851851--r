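## Cohort parameter modeling: factor analysis, random-forest screening of
## predictors, penalized negative-binomial additive models of cohort size
## and longevity, and temporal trend tests.

.factor_default_cols <- c("N", "singles", "PA", "juveniles_1yr", "Ad",
                          "understory_1yr", "life_mn", "st_max_mn")

#' Factor analysis of cohort parameters
#'
#' Maximum-likelihood factor analysis (varimax rotation, regression
#' scores) of the numeric cohort parameters, used to group parameters into
#' a cohort-size axis and a cohort-longevity axis.
#'
#' @param cohorts a `kelp_cohorts` table or numeric matrix/data frame.
#' @param n_factors number of factors (default 2).
#' @param columns columns to include; default a standard set of cohort
#'   demography parameters.
#' @return a `kelp_factors` object: `loadings`, `variance_share` (per
#'   factor, fraction of total variance), `scores`, `rotation`.
#' @export
factor_model <- function(cohorts, n_factors = 2, columns = NULL) {
  if (is.null(columns))
    columns <- if (all(.factor_default_cols %in% names(cohorts)))
      .factor_default_cols else names(cohorts)[vapply(cohorts, is.numeric, TRUE)]
  x <- as.data.frame(cohorts)[, columns]
  x <- x[stats::complete.cases(x), , drop = FALSE]
  if (ncol(x) < 3) stopf("factor analysis needs at least 3 parameters")
  if (nrow(x) < n_factors + 1)
    stopf("factor analysis needs more cohorts than factors")
  xs <- scale(x)
  if (any(!is.finite(xs))) stopf("constant column in factor analysis input")
  fit <- tryCatch(
    stats::factanal(xs, factors = n_factors, rotation = "varimax",
                    scores = "regression"),
    error = function(e) stopf("factor analysis failed: %s", conditionMessage(e)))
  L <- unclass(fit$loadings)
  structure(list(loadings = L,
                 variance_share = colSums(L^2) / ncol(x),
                 scores = fit$scores, rotation = "varimax",
                 uniquenesses = fit$uniquenesses, n = nrow(x),
                 columns = columns),
            class = "kelp_factors")
}

#' @export
print.kelp_factors <- function(x, digits = 2, ...) {
  cat(sprintf("Factor analysis (varimax, regression scores): %d cohorts, %d factors\n",
              x$n, ncol(x$loadings)))
  cat("variance shares:",
      paste(sprintf("%.0f%%", 100 * x$variance_share), collapse = ", "), "\n")
  print(round(x$loadings, digits))
  invisible(x)
}

#' Screen predictors by random-forest importance
#'
#' Permutation importance from a seeded regression random forest, used to
#' shortlist cohort parameters as candidate GAM covariates.
#'
#' @param data a data frame of cohort parameters.
#' @param response name of the response column.
#' @param predictors candidate columns (default: all other numeric columns).
#' @param n_trees number of trees (default 500).
#' @param seed RNG seed.
#' @return data frame `predictor`, `importance` (%IncMSE), sorted
#'   decreasing; attribute `"unstable"` set when fewer than 10 rows.
#' @export
screen_predictors <- function(data, response, predictors = NULL,
                              n_trees = 500, seed = 1) {
  if (is.null(predictors)) {
    num <- names(data)[vapply(data, is.numeric, TRUE)]
    predictors <- setdiff(num, response)
  }
  d <- as.data.frame(data)[, c(response, predictors)]
  d <- d[stats::complete.cases(d), ]
  unstable <- nrow(d) < 10
  if (unstable) warnf("only %d cohorts: importance ranking is unstable", nrow(d))
  rf <- with_seed(seed,
    randomForest::randomForest(x = d[, predictors, drop = FALSE],
                               y = d[[response]], ntree = n_trees,
                               importance = TRUE))
  imp <- randomForest::importance(rf, type = 1)
  out <- data.frame(predictor = rownames(imp), importance = imp[, 1])
  out <- out[order(-out$importance), ]
  rownames(out) <- NULL
  attr(out, "unstable") <- unstable
  out
}

## Decade factor with the 2000s as reference level (when present).
decade_factor <- function(decade, reference = "2000s") {
  f <- factor(decade)
  if (reference %in% levels(f)) stats::relevel(f, ref = reference) else f
}

## Shared machinery for the two additive models.
fit_nb_gam <- function(df, response, smooth_vars, k = 10, family = "nb") {
  df$.decade <- decade_factor(df$decade)
  lev_n <- table(df$.decade)
  if (any(lev_n < 2)) {
    # a decade represented by a single cohort is fit perfectly by its own
    # contrast; drop such levels rather than report a meaningless z
    drop <- names(lev_n)[lev_n < 2]
    warnf("dropping decade level(s) with fewer than 2 cohorts: %s",
          paste(drop, collapse = ", "))
    df <- df[!df$.decade %in% drop, , drop = FALSE]
    df$.decade <- droplevels(df$.decade)
  }
  if (nlevels(df$.decade) < 2)
    stopf("decade factor is degenerate (%d level(s))", nlevels(df$.decade))
  if (nrow(df) < 30) warnf("only %d cohorts: additive model may be unstable", nrow(df))
  terms <- vapply(smooth_vars, function(v) {
    kk <- min(k, max(3, length(unique(df[[v]])) - 1))
    sprintf("s(%s, k = %d)", v, kk)
  }, "")
  fml <- stats::as.formula(paste(response, "~ .decade +", paste(terms, collapse = " + ")))
  fam <- switch(family, nb = mgcv::nb(), gaussian = stats::gaussian(link = "log"))
  fit <- mgcv::gam(fml, data = df, family = fam, method = "GCV.Cp", select = TRUE)
  s <- summary(fit)
  smooths <- lapply(smooth_vars, function(v) {
    grid <- df[rep(1, 100), , drop = FALSE]
    for (w in smooth_vars) grid[[w]] <- stats::median(df[[w]], na.rm = TRUE)
    grid[[v]] <- seq(min(df[[v]], na.rm = TRUE), max(df[[v]], na.rm = TRUE),
                     length.out = 100)
    grid$.decade <- factor(levels(df$.decade)[1], levels = levels(df$.decade))
    tm <- stats::predict(fit, newdata = grid, type = "terms")
    col <- grep(sprintf("s\\(%s", v), colnames(tm))
    data.frame(x = grid[[v]], partial = tm[, col[1]])
  })
  names(smooths) <- smooth_vars
  ptab <- s$p.table
  rownames(ptab) <- sub("^\\.decade", "decade", rownames(ptab))
  structure(list(fit = fit, response = response, smooth_vars = smooth_vars,
                 parametric = ptab, smooth_table = s$s.table,
                 dev_expl = as.numeric(s$dev.expl), r_sq = as.numeric(s$r.sq),
                 smooths = smooths, n = nrow(df), family = family),
            class = "kelp_gam")
}

#' Additive model of cohort size
#'
#' Negative-binomial generalized additive model of the number of plants
#' per cohort on smooths of the prior adult count (potential spore
#' provisioning) and of understory prevalence in the year before onset,
#' with calendar decade as a parametric factor (reference: 2000s).
#' Smoothness is selected by generalized cross-validation with
#' double-penalty shrinkage, which can remove a term entirely
#' (effective df near 0). Cohorts still alive at the series end are
#' excluded.
#'
#' @param cohorts a `kelp_cohorts` table.
#' @param k basis dimension per smooth (default 10).
#' @param family `"nb"` (default) or `"gaussian"` (log link), the latter
#'   for a continuous-response sensitivity fit.
#' @return a `kelp_gam` object with Table-style parametric and smooth-term
#'   summaries and partial-effect evaluation grids.
#' @export
fit_cohort_size_model <- function(cohorts, k = 10, family = "nb") {
  df <- as.data.frame(cohorts)[!cohorts$alive, ]
  df <- df[stats::complete.cases(df[, c("N", "Ad", "understory_1yr", "decade")]), ]
  fit_nb_gam(df, "N", c("Ad", "understory_1yr"), k = k, family = family)
}

#' Additive model of cohort longevity
#'
#' Negative-binomial generalized additive model of cohort mean lifespan
#' (rounded to integer days to satisfy the count family) on smooths of the
#' 80th-percentile bottom temperature, 80th-percentile weekly wave energy,
#' and purple and red sea urchin densities over each cohort's lifetime
#' window, with decade as a parametric factor. Same smoothness selection
#' as [fit_cohort_size_model()]; cohorts still alive are excluded.
#'
#' @inheritParams fit_cohort_size_model
#' @return a `kelp_gam` object. The wave partial-effect grid
#'   (`$smooths$wave80`) locates the rise/sill/decline shape of the wave
#'   response.
#' @export
fit_longevity_model <- function(cohorts, k = 10, family = "nb") {
  df <- as.data.frame(cohorts)[!cohorts$alive, ]
  vars <- c("temp80", "wave80", "psu_density", "rsu_density")
  df <- df[stats::complete.cases(df[, c("life_mn", vars, "decade")]), ]
  df$life_days <- as.integer(round(df$life_mn * 365.25))
  fit_nb_gam(df, "life_days", vars, k = k, family = family)
}

#' @export
print.kelp_gam <- function(x, digits = 3, ...) {
  cat(sprintf("Penalized additive model of %s (%s family, GCV + shrinkage), n = %d\n",
              x$response, x$family, x$n))
  cat("Parametric coefficients\n")
  print(round(x$parametric, digits))
  cat("Significance of smooth terms\n")
  print(round(x$smooth_table, digits))
  cat(sprintf("R-sq (adj) = %.3f; deviance explained = %.1f%%\n",
              x$r_sq, 100 * x$dev_expl))
  invisible(x)
}

#' @export
plot.kelp_gam <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, length(x$smooths)))
  on.exit(graphics::par(op))
  for (v in names(x$smooths))
    graphics::plot(x$smooths[[v]]$x, x$smooths[[v]]$partial, type = "l",
                   xlab = v, ylab = sprintf("partial effect on log %s", x$response), ...)
  invisible(x)
}

#' Temporal trend tests of cohort structure
#'
#' Ordinary least squares of cohort size on onset date (slope, F, p), and
#' logistic regression of the trickled/pulsed indicator (trickled = 1) on
#' onset date (coefficient, z, p). The logistic fit is flagged degenerate
#' when all cohorts share one class.
#'
#' @param cohorts a `kelp_cohorts` table.
#' @return a `kelp_trends` object.
#' @export
trend_tests <- function(cohorts) {
  if (nrow(cohorts) < 10) warnf("trend tests on only %d cohorts", nrow(cohorts))
  lmfit <- stats::lm(N ~ onset_date, data = cohorts)
  sl <- summary(lmfit)
  fstat <- sl$fstatistic
  size <- list(slope = unname(stats::coef(lmfit)[2]),
               intercept = unname(stats::coef(lmfit)[1]),
               F = unname(fstat[1]), df = unname(fstat[2:3]),
               p = unname(stats::pf(fstat[1], fstat[2], fstat[3],
                                    lower.tail = FALSE)))
  trick <- as.integer(!cohorts$pulsed)
  degenerate <- length(unique(trick)) < 2
  logit <- if (degenerate) {
    list(coef = NA_real_, z = NA_real_, p = NA_real_, degenerate = TRUE)
  } else {
    gl <- stats::glm(trick ~ onset_date, data = cohorts, family = stats::binomial())
    cs <- summary(gl)$coefficients
    list(coef = cs[2, 1], z = cs[2, 3], p = cs[2, 4], degenerate = FALSE)
  }
  structure(list(size_trend = size, trickled_trend = logit, n = nrow(cohorts)),
            class = "kelp_trends")
}

#' @export
print.kelp_trends <- function(x, ...) {
  s <- x$size_trend
  cat(sprintf("Cohort size vs time: slope = %.3f /yr, F[%d,%d] = %.2f, p = %.3g\n",
              s$slope, s$df[1], s$df[2], s$F, s$p))
  t <- x$trickled_trend
  if (isTRUE(t$degenerate)) cat("Trickledness vs time: degenerate (single class)\n")
  else cat(sprintf("Trickledness vs time (logit): coef = %.3f /yr, z = %.2f, p = %.3g\n",
                   t$coef, t$z, t$p))
  invisible(x)
}
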