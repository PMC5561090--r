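# Developmental and time trends in Wi: linear subset trends, penalized-spline
# smooths, predictor comparison (R2, AIC), cross-species mixed model, and
# backward-looking time-trend reconstruction with study weighting.

PREDICTOR_COLUMNS <- c(age = "age_years", height = "height_m",
                       diameter = "dbh_cm", cii = "cii_ordinal",
                       calendar_year = "year")

# Slopes are reported in the field's customary units: ppm per 100 yr for
# per-year predictors, ppm per 10 m for height; diameter and crown
# illumination stay per-unit (cm, class step).
slope_scale <- function(predictor) {
  switch(predictor,
         age = 100, calendar_year = 100, height = 10,
         diameter = 1, cii = 1)
}

slope_units <- function(predictor) {
  switch(predictor,
         age = "ppm (100 yr)^-1", calendar_year = "ppm (100 yr)^-1",
         height = "ppm (10 m)^-1", diameter = "ppm cm^-1",
         cii = "ppm (CII step)^-1")
}

#' Linear trend in Wi against a developmental or temporal predictor
#'
#' Ordinary least-squares fit of Wi on a single predictor, with the slope
#' rescaled to reporting units (ppm per 100 yr for age and calendar year,
#' ppm per 10 m for height). Standard error, two-sided p-value and R-squared
#' come from standard linear-model theory.
#'
#' @param x Predictor values (years, m, cm or CII ordinal steps).
#' @param y Wi in ppm.
#' @param predictor One of `"age"`, `"height"`, `"diameter"`, `"cii"`,
#'   `"calendar_year"`; controls the reporting scale.
#' @param subset_rule Free-text descriptor of the subset fitted (e.g.
#'   `"age > 50 yr"`); recorded in the result.
#' @return An object of class `trend_fit`: a list with `predictor`, `slope`
#'   (reporting units), `slope_raw` (per predictor unit), `slope_se`,
#'   `p_value`, `r_squared`, `n`, `units`, `subset_rule`.
#' @examples
#' fit <- linear_trend(1:20, 60 + 0.1 * (1:20), "age")
#' fit$slope  # 10 ppm per 100 yr
#' @export
linear_trend <- function(x, y,
                         predictor = c("age", "height", "diameter", "cii",
                                       "calendar_year"),
                         subset_rule = "full range") {
  predictor <- match.arg(predictor)
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3)
    stop("linear_trend requires at least 3 observations")
  if (stats::var(x) == 0)
    stop("degenerate design: predictor is constant")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  slope_raw <- unname(stats::coef(fit)[2])
  if (stats::var(y) == 0) {
    slope_raw <- 0
    se <- 0
    p <- NA_real_
    r2 <- 0
  } else {
    se <- sm$coefficients[2, 2]
    p <- sm$coefficients[2, 4]
    r2 <- sm$r.squared
  }
  scale <- slope_scale(predictor)
  structure(list(predictor = predictor,
                 slope = slope_raw * scale,
                 slope_raw = slope_raw,
                 slope_se = se * scale,
                 p_value = p,
                 r_squared = r2,
                 n = length(x),
                 units = slope_units(predictor),
                 subset_rule = subset_rule),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("Linear Wi trend vs %s [%s]\n", x$predictor, x$subset_rule))
  cat(sprintf("  slope %.3f +/- %.3f %s, R^2 = %.3f, p = %s, n = %d\n",
              x$slope, x$slope_se, x$units, x$r_squared,
              format.pval(x$p_value, digits = 3), x$n))
  invisible(x)
}

#' Trends after excluding earlier life stages
#'
#' Refits the linear Wi trend using only records above each threshold of the
#' predictor (strict `>`), mirroring analyses that exclude the first decades
#' of age or the first metres of height. Subsets with fewer than `min_n`
#' usable records are reported as not estimable rather than silently
#' dropped.
#'
#' @param data Data frame with a `wi_ppm` column and the predictor column
#'   (`age_years`, `height_m`, ...). Rows flagged `out_of_range` are
#'   excluded first when that column is present.
#' @param predictor `"age"`, `"height"`, `"diameter"` or `"cii"`.
#' @param thresholds Ascending numeric thresholds; use `-Inf` for the
#'   full-range fit.
#' @param min_n Minimum records for an estimable fit. Default 3.
#' @return Data frame with one row per threshold: threshold, n, slope,
#'   slope_se, p_value, r_squared, estimable.
#' @export
threshold_subset_trends <- function(data, predictor, thresholds, min_n = 3) {
  if (is.unsorted(thresholds))
    stop("thresholds must be sorted ascending")
  col <- PREDICTOR_COLUMNS[[predictor]]
  data <- drop_flagged(data)
  out <- lapply(thresholds, function(th) {
    sub <- data[!is.na(data[[col]]) & data[[col]] > th, , drop = FALSE]
    n_ok <- sum(!is.na(sub$wi_ppm))
    est <- n_ok >= min_n && n_ok > 0 &&
      length(unique(sub[[col]][!is.na(sub$wi_ppm)])) > 1
    if (est) {
      fit <- linear_trend(sub[[col]], sub$wi_ppm, predictor,
                          subset_rule = sprintf("%s > %g", predictor, th))
      data.frame(threshold = th, n = fit$n, slope = fit$slope,
                 slope_se = fit$slope_se, p_value = fit$p_value,
                 r_squared = fit$r_squared, estimable = TRUE)
    } else {
      data.frame(threshold = th, n = n_ok, slope = NA_real_,
                 slope_se = NA_real_, p_value = NA_real_,
                 r_squared = NA_real_, estimable = FALSE)
    }
  })
  do.call(rbind, out)
}

drop_flagged <- function(data) {
  if ("out_of_range" %in% names(data))
    data <- data[!data$out_of_range, , drop = FALSE]
  data
}

#' Exclude trees below a minimum height
#'
#' Removes trees shorter than `min_height_m` (strictly lower; the boundary
#' is kept). Small understory trees assimilate a substantial share of
#' soil-respired CO2, so they are excluded from age-trend analyses that are
#' meant to be comparable with conventional tree-ring sampling at breast
#' height.
#'
#' @param data Data frame with a `height_m` column.
#' @param min_height_m Minimum height kept, m. Default 1.
#' @return The subset, with a message reporting how many trees were removed.
#' @export
exclude_small_trees <- function(data, min_height_m = 1.0) {
  if (!"height_m" %in% names(data)) stop("data must have a height_m column")
  drop <- !is.na(data$height_m) & data$height_m < min_height_m
  out <- data[!drop, , drop = FALSE]
  message(sprintf("excluded %d tree(s) below %g m", sum(drop), min_height_m))
  if (nrow(out) == 0)
    warning("all trees excluded; returning empty subset", call. = FALSE)
  out
}

#' Penalized-spline smooth of Wi against a predictor
#'
#' Fits a cubic penalized regression spline (thin-plate basis, smoothing
#' strength chosen by generalized cross-validation via [mgcv::gam()]) and
#' returns the mean curve with pointwise standard errors on a regular grid.
#' When group identifiers are supplied, a per-group constant offset is
#' absorbed by backfitting before the final smooth — a random-intercept
#' surrogate that keeps the displayed mean curve free of between-tree or
#' between-study level differences.
#'
#' @param x Predictor values.
#' @param y Wi (ppm).
#' @param groups Optional group labels (tree or study ids).
#' @param grid_n Number of grid points for the returned curve. Default 100.
#' @param k Spline basis dimension passed to `s()`. Default 10 (reduced
#'   automatically for small samples).
#' @return An object of class `smooth_fit`: list with `grid`, `mean`, `se`,
#'   `sp` (selected smoothing parameter), `offsets` (per-group, or NULL) and
#'   the underlying `gam` fit.
#' @export
smooth_trend <- function(x, y, groups = NULL, grid_n = 100, k = 10) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  if (!is.null(groups)) groups <- factor(groups[keep])
  if (length(unique(x)) < 10)
    stop("too few distinct predictor values for a smooth; use linear_trend")
  k <- min(k, length(unique(x)) - 1)
  offsets <- NULL
  y_adj <- y
  if (!is.null(groups) && nlevels(groups) > 1) {
    g_off <- stats::setNames(rep(0, nlevels(groups)), levels(groups))
    for (iter in 1:5) {
      fit0 <- mgcv::gam(y_adj ~ s(x, k = k), method = "GCV.Cp")
      res <- y_adj - stats::fitted(fit0)
      step <- tapply(res, groups, mean)
      # keep the overall level: observation-weighted mean offset stays zero
      step <- step - stats::weighted.mean(step, table(groups))
      g_off <- g_off + step
      y_adj <- y - g_off[as.character(groups)]
      if (max(abs(step)) < 1e-10) break
    }
    offsets <- g_off
  }
  fit <- mgcv::gam(y_adj ~ s(x, k = k), method = "GCV.Cp")
  grid <- seq(min(x), max(x), length.out = grid_n)
  pred <- mgcv::predict.gam(fit, newdata = data.frame(x = grid),
                            se.fit = TRUE)
  structure(list(grid = grid, mean = as.numeric(pred$fit),
                 se = as.numeric(pred$se.fit), sp = unname(fit$sp),
                 offsets = offsets, fit = fit),
            class = "smooth_fit")
}

#' @export
print.smooth_fit <- function(x, ...) {
  cat(sprintf(
    "Penalized-spline smooth: %d grid points, smoothing parameter %.4g\n",
    length(x$grid), x$sp[1]))
  invisible(x)
}

#' Univariate explanatory power of each developmental predictor
#'
#' For each of age, diameter, height and crown illumination (ordinal),
#' computes the R-squared and p-value of the univariate linear model of Wi
#' on that predictor. Predictors that are constant or have fewer than 3
#' usable records are flagged not estimable.
#'
#' @param data Data frame with `wi_ppm` and the predictor columns
#'   `age_years`, `dbh_cm`, `height_m`, `cii_ordinal`.
#' @return Data frame with one row per predictor: r_squared, p_value, n,
#'   estimable.
#' @export
per_predictor_r2 <- function(data) {
  data <- drop_flagged(data)
  preds <- c("age", "diameter", "height", "cii")
  rows <- lapply(preds, function(p) {
    col <- PREDICTOR_COLUMNS[[p]]
    x <- data[[col]]
    y <- data$wi_ppm
    keep <- !is.na(x) & !is.na(y)
    if (sum(keep) < 3 || length(unique(x[keep])) < 2)
      return(data.frame(predictor = p, r_squared = NA_real_,
                        p_value = NA_real_, n = sum(keep),
                        estimable = FALSE))
    fit <- linear_trend(x[keep], y[keep], p)
    data.frame(predictor = p, r_squared = fit$r_squared,
               p_value = fit$p_value, n = fit$n, estimable = TRUE)
  })
  do.call(rbind, rows)
}

#' Most parsimonious predictor set by AIC
#'
#' Fits all main-effects linear models of Wi on subsets of {age, diameter,
#' height, cii} (including the intercept-only model) on the common set of
#' complete cases, ranks them by the Akaike Information Criterion and
#' returns the minimum-AIC model. Exact AIC ties break deterministically to
#' the smaller predictor set, then lexicographically.
#'
#' @param data Data frame with `wi_ppm`, `age_years`, `dbh_cm`, `height_m`,
#'   `cii_ordinal`.
#' @param predictors Candidate predictors. Default all four.
#' @return An object of class `model_selection`: list with `table` (one row
#'   per candidate: predictors, k, aic, r_squared), `selected` (character
#'   vector of predictors) and `variance_explained` (R-squared of the
#'   selected model).
#' @export
model_selection_aic <- function(data,
                                predictors = c("age", "diameter", "height",
                                               "cii")) {
  data <- drop_flagged(data)
  cols <- PREDICTOR_COLUMNS[predictors]
  use <- stats::complete.cases(data[, c("wi_ppm", cols)])
  d <- data[use, , drop = FALSE]
  if (nrow(d) < 10)
    stop("model selection requires at least 10 complete cases")
  sets <- unlist(lapply(0:length(predictors), function(m)
    utils::combn(predictors, m, simplify = FALSE)), recursive = FALSE)
  rows <- lapply(sets, function(s) {
    rhs <- if (length(s) == 0) "1" else
      paste(PREDICTOR_COLUMNS[s], collapse = " + ")
    fit <- stats::lm(stats::as.formula(paste("wi_ppm ~", rhs)), data = d)
    data.frame(predictors = paste(s, collapse = "+"), k = length(s),
               aic = stats::AIC(fit),
               r_squared = summary(fit)$r.squared)
  })
  tab <- do.call(rbind, rows)
  ord <- order(tab$aic, tab$k, tab$predictors)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  best <- tab$predictors[1]
  selected <- if (best == "") character(0) else
    strsplit(best, "+", fixed = TRUE)[[1]]
  structure(list(table = tab, selected = selected,
                 variance_explained = tab$r_squared[1], n = nrow(d)),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  sel <- if (length(x$selected) == 0) "(intercept only)" else
    paste(x$selected, collapse = ", ")
  cat(sprintf("AIC model selection (n = %d): %s, variance explained %.1f%%\n",
              x$n, sel, 100 * x$variance_explained))
  invisible(x)
}

#' Cross-species mixed-effects model of Wi
#'
#' Linear mixed model of Wi on age, diameter, height and crown illumination
#' with species-level random intercepts, estimated by REML. Fixed-effect
#' t-values use Satterthwaite degrees of freedom for the p-values. With a
#' single species the model degenerates and an ordinary fixed-effects fit is
#' returned with a warning.
#'
#' Note that because age, size and light are strongly interdependent in a
#' developing stand, the conditional (partial) age effect can take the
#' opposite sign from the marginal age trend.
#'
#' @param data Data frame with `wi_ppm`, `species`, `age_years`, `dbh_cm`,
#'   `height_m`, `cii_ordinal`.
#' @return An object of class `mixed_fit`: list with `coefficients` (data
#'   frame: predictor, estimate, se, t_value, p_value), `species_sd`
#'   (random-intercept standard deviation; 0 for the fixed-effects
#'   fallback), `n`, `n_species` and the underlying fit.
#' @export
mixed_effects_all_species <- function(data) {
  data <- drop_flagged(data)
  cols <- c("wi_ppm", "species", "age_years", "dbh_cm", "height_m",
            "cii_ordinal")
  d <- data[stats::complete.cases(data[, cols]), cols]
  n_species <- length(unique(d$species))
  form_fixed <- wi_ppm ~ age_years + dbh_cm + height_m + cii_ordinal
  if (n_species < 2) {
    warning("single species: falling back to a fixed-effects linear model",
            call. = FALSE)
    fit <- stats::lm(form_fixed, data = d)
    cf <- summary(fit)$coefficients
    co <- data.frame(predictor = rownames(cf)[-1], estimate = cf[-1, 1],
                     se = cf[-1, 2], t_value = cf[-1, 3],
                     p_value = cf[-1, 4], row.names = NULL)
    return(structure(list(coefficients = co, species_sd = 0, n = nrow(d),
                          n_species = n_species, fit = fit),
                     class = "mixed_fit"))
  }
  fit <- lmerTest::lmer(
    wi_ppm ~ age_years + dbh_cm + height_m + cii_ordinal + (1 | species),
    data = d, REML = TRUE)
  cf <- stats::coef(summary(fit))
  co <- data.frame(predictor = rownames(cf)[-1], estimate = cf[-1, "Estimate"],
                   se = cf[-1, "Std. Error"], t_value = cf[-1, "t value"],
                   p_value = cf[-1, "Pr(>|t|)"], row.names = NULL)
  vc <- as.data.frame(lme4::VarCorr(fit))
  species_sd <- vc$sdcor[vc$grp == "species"][1]
  structure(list(coefficients = co, species_sd = species_sd, n = nrow(d),
                 n_species = n_species, fit = fit),
            class = "mixed_fit")
}

#' @export
print.mixed_fit <- function(x, ...) {
  cat(sprintf(
    "Mixed model of Wi (%d trees, %d species), species SD = %.2f ppm\n",
    x$n, x$n_species, x$species_sd))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Backward-looking time trend from ring series
#'
#' Converts each tree's dated ring delta13C series to Wi against the
#' year-matched atmosphere, fits a per-series linear trend in calendar year,
#' and combines the per-series slopes as a weighted mean with weights
#' proportional to the supplied study-site counts (default: equal weights,
#' which coincides exactly with the unweighted estimate). A pooled
#' penalized-spline curve across all series (per-tree offsets absorbed) is
#' returned alongside.
#'
#' This is the classical chronology construction: it looks backwards through
#' the lifetime of today's large trees, and therefore inherits their full
#' developmental trajectory.
#'
#' @param rings A `ring_table` (see [read_ring_table()]).
#' @param atmos Atmospheric record covering all ring years.
#' @param weights Optional named numeric vector of weights keyed by
#'   `tree_id` (e.g. number of study sites per source); default 1 for every
#'   series.
#' @param constants [isotope_constants()].
#' @param min_series_n Minimum dated observations per series. Default 3.
#' @return An object of class `time_trend`: list with `slope` (weighted mean
#'   slope, ppm per 100 yr), `slope_se`, `per_series` (data frame of
#'   per-series fits), `smooth` (`smooth_fit` or NULL), `wi` (per-ring Wi
#'   table).
#' @export
time_trend <- function(rings, atmos, weights = NULL,
                       constants = isotope_constants(), min_series_n = 3) {
  ids <- unique(rings$tree_id)
  state <- gas_exchange_state(rings$d13c_permil, rings$calendar_year, atmos,
                              constants)
  wi_tab <- data.frame(tree_id = rings$tree_id,
                       calendar_year = rings$calendar_year,
                       wi_ppm = state$wi_ppm,
                       out_of_range = state$out_of_range)
  per <- lapply(ids, function(id) {
    sub <- wi_tab[wi_tab$tree_id == id & !wi_tab$out_of_range, ]
    if (nrow(sub) < min_series_n || length(unique(sub$calendar_year)) < 2)
      return(data.frame(tree_id = id, slope = NA_real_, slope_se = NA_real_,
                        n = nrow(sub), estimable = FALSE))
    fit <- linear_trend(sub$calendar_year, sub$wi_ppm, "calendar_year",
                        subset_rule = sprintf("series %s", id))
    data.frame(tree_id = id, slope = fit$slope, slope_se = fit$slope_se,
               n = fit$n, estimable = TRUE)
  })
  per <- do.call(rbind, per)
  est <- per[per$estimable, , drop = FALSE]
  if (nrow(est) == 0) stop("no series long enough for a time trend")
  w <- if (is.null(weights)) rep(1, nrow(est)) else {
    if (is.null(names(weights)))
      stop("weights must be a named vector keyed by tree_id")
    miss <- setdiff(est$tree_id, names(weights))
    if (length(miss) > 0)
      stop(sprintf("no weight supplied for series: %s",
                   paste(miss, collapse = ", ")))
    unname(weights[est$tree_id])
  }
  slope <- stats::weighted.mean(est$slope, w)
  slope_se <- if (nrow(est) > 1) {
    sqrt(sum(w * (est$slope - slope)^2) / sum(w) / (nrow(est) - 1))
  } else est$slope_se[1]
  ok <- !wi_tab$out_of_range
  smooth <- NULL
  if (length(unique(wi_tab$calendar_year[ok])) >= 10) {
    smooth <- smooth_trend(wi_tab$calendar_year[ok], wi_tab$wi_ppm[ok],
                           groups = wi_tab$tree_id[ok])
  }
  structure(list(slope = slope, slope_se = slope_se, per_series = per,
                 smooth = smooth, wi = wi_tab),
            class = "time_trend")
}

#' @export
print.time_trend <- function(x, ...) {
  cat(sprintf(
    "Reconstructed time trend: %.2f +/- %.2f ppm (100 yr)^-1 from %d series\n",
    x$slope, x$slope_se, sum(x$per_series$estimable)))
  invisible(x)
}

#' Cubic smoothing spline of an annual series
#'
#' Display smoother for individual annual Wi series: a cubic smoothing
#' spline evaluated at the observed years. Series with fewer than 4 points
#' are returned unchanged with a warning.
#'
#' @param year Observation years.
#' @param value Series values.
#' @param spar Smoothing parameter passed to [stats::smooth.spline()];
#'   `NULL` selects it by generalized cross-validation.
#' @return Data frame with `year`, `value`, `smoothed`.
#' @export
spline_smooth_series <- function(year, value, spar = NULL) {
  keep <- !is.na(year) & !is.na(value)
  year <- year[keep]
  value <- value[keep]
  if (length(unique(year)) < 4) {
    warning("fewer than 4 distinct years: returning the series unsmoothed",
            call. = FALSE)
    return(data.frame(year = year, value = value, smoothed = value))
  }
  fit <- if (is.null(spar)) stats::smooth.spline(year, value) else
    stats::smooth.spline(year, value, spar = spar)
  data.frame(year = year, value = value,
             smoothed = stats::predict(fit, year)$y)
}
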