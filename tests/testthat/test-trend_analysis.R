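test_that("linear trends match hand OLS and use reporting units", {
  # exact line: 0.1 ppm/yr -> 10 ppm per 100 yr
  x <- 1:20
  fit <- suppressWarnings(linear_trend(x, 5 + 0.1 * x, "age"))
  expect_equal(fit$slope, 10, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  # flat response: zero slope, zero R2
  flat <- suppressWarnings(linear_trend(x, rep(3, 20), "age"))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)

  # hand-computed OLS: Sxy/Sxx = 4/5 per unit
  fit2 <- linear_trend(c(1, 2, 3, 4), c(2, 2, 4, 4), "cii")
  expect_equal(fit2$slope, 0.8, tolerance = 1e-12)

  # height slopes reported per 10 m
  h <- c(2, 5, 9, 14, 22)
  fith <- suppressWarnings(linear_trend(h, 60 + 1.8 * h, "height"))
  expect_equal(fith$slope, 18, tolerance = 1e-9)

  expect_error(linear_trend(1:2, 1:2, "age"), "at least 3")
  expect_error(linear_trend(rep(1, 5), 1:5, "age"), "degenerate")
})

test_that("linear_trend equals the sums-based OLS oracle on random data", {
  set.seed(99)
  for (i in 1:50) {
    n <- sample(5:50, 1)
    x <- rnorm(n, sd = runif(1, 0.5, 20))
    y <- rnorm(n, mean = 2 * x, sd = runif(1, 0.1, 10))
    fit <- linear_trend(x, y, "cii")
    or <- oracle_ols(x, y)
    expect_equal(fit$slope_raw, or$slope, tolerance = 1e-10)
    expect_equal(fit$slope_se, or$se, tolerance = 1e-10)
    expect_equal(fit$r_squared, or$r_squared, tolerance = 1e-10)
    expect_equal(fit$p_value, or$p, tolerance = 1e-10)
  }
})

test_that("threshold subsets behave as documented", {
  # piecewise: slope 2 below x = 50, slope 1 above
  x <- seq(1, 100, by = 1)
  y <- ifelse(x <= 50, 2 * x, 100 + 1 * (x - 50))
  d <- data.frame(age_years = x, wi_ppm = y)
  res <- suppressWarnings(
    threshold_subset_trends(d, "age", c(-Inf, 50)))
  full <- res$slope[1] / 100   # back to per-unit
  expect_gt(full, 1)
  expect_lt(full, 2)
  expect_equal(res$slope[2] / 100, 1, tolerance = 1e-9)

  # all data above the largest threshold: identical slopes everywhere
  d2 <- data.frame(age_years = 300 + 1:30,
                   wi_ppm = 50 + 0.3 * (1:30) + sin(1:30))
  res2 <- threshold_subset_trends(d2, "age", c(-Inf, 25, 100, 200))
  expect_true(all(abs(res2$slope - res2$slope[1]) < 1e-9))

  # a threshold leaving 2 points is not estimable, not dropped
  res3 <- suppressWarnings(threshold_subset_trends(d, "age", c(98)))
  expect_false(res3$estimable[1])
  expect_true(is.na(res3$slope[1]))
  expect_error(threshold_subset_trends(d, "age", c(50, 25)), "ascending")
})

test_that("small-tree exclusion keeps the 1 m boundary", {
  d <- data.frame(height_m = c(0.5, 1.0, 2.0), wi_ppm = 1:3)
  kept <- suppressMessages(exclude_small_trees(d))
  expect_equal(kept$height_m, c(1.0, 2.0))
  all_tall <- data.frame(height_m = c(1, 3), wi_ppm = 1:2)
  expect_equal(suppressMessages(exclude_small_trees(all_tall)), all_tall)
  expect_warning(suppressMessages(
    exclude_small_trees(data.frame(height_m = 0.2, wi_ppm = 1))),
    "empty")
})

test_that("penalized-spline smooth reproduces lines and recovers curves", {
  # exactly linear data: the smooth is the OLS line
  x <- seq(0, 10, length.out = 60)
  y <- 2 + 3 * x
  sm <- smooth_trend(x, y)
  expect_lt(max(abs(sm$mean - (2 + 3 * sm$grid))), 1e-6)

  # sin + noise: curve RMSE beats the noise sd
  set.seed(21)
  x2 <- sort(runif(200, 0, 2 * pi))
  y2 <- sin(x2) + rnorm(200, 0, 0.3)
  sm2 <- smooth_trend(x2, y2)
  rmse <- sqrt(mean((sm2$mean - sin(sm2$grid))^2))
  expect_lt(rmse, 0.3)
  expect_true(all(sm2$se > 0))
  expect_true(all(diff(sm2$grid) > 0))

  expect_error(smooth_trend(1:5, 1:5), "too few")
})

test_that("group offsets are absorbed before smoothing", {
  set.seed(22)
  x <- rep(seq(0, 10, length.out = 50), 2)
  g <- rep(c("A", "B"), each = 50)
  base <- 5 + 2 * sin(x / 2)
  y <- base + ifelse(g == "B", 10, 0) + rnorm(100, 0, 0.2)
  sm_grp <- smooth_trend(x, y, groups = g)
  sm_one <- smooth_trend(x[1:50], y[1:50] + 5, grid_n = 100)  # level-matched
  # de-offset curve sits between the groups, close to the shared shape + mean offset
  expect_lt(max(abs(sm_grp$mean - sm_one$mean)), 2 * max(sm_grp$se + sm_one$se))
  expect_equal(unname(diff(sm_grp$offsets)), 10, tolerance = 0.5)
})

test_that("univariate R2 reflects the generating structure", {
  set.seed(23)
  n <- 120
  h <- runif(n, 1, 30)
  d <- data.frame(age_years = sample(1:100, n, TRUE), dbh_cm = runif(n, 1, 50),
                  height_m = h, cii_ordinal = sample(1:8, n, TRUE),
                  wi_ppm = 60 + 1.8 * h + rnorm(n, 0, 0.5))
  r2 <- per_predictor_r2(d)
  expect_gt(r2$r_squared[r2$predictor == "height"], 0.98)
  expect_lt(max(r2$r_squared[r2$predictor != "height"]), 0.2)

  # constant predictor flagged not estimable
  d$cii_ordinal <- 4L
  r2c <- per_predictor_r2(d)
  expect_false(r2c$estimable[r2c$predictor == "cii"])
})

test_that("null predictors are significant at the nominal type-I rate", {
  set.seed(24)
  reject <- logical(400)
  for (i in seq_along(reject)) {
    n <- 30
    d <- data.frame(age_years = sample(1:100, n, TRUE),
                    dbh_cm = runif(n, 1, 50),
                    height_m = runif(n, 1, 30),
                    cii_ordinal = sample(1:8, n, TRUE),
                    wi_ppm = rnorm(n, 80, 10))
    r2 <- per_predictor_r2(d)
    reject[i] <- r2$p_value[r2$predictor == "height"] < 0.05
  }
  expect_gt(mean(reject), 0.01)
  expect_lt(mean(reject), 0.10)
})

test_that("AIC selection finds the generating predictors and breaks ties", {
  set.seed(25)
  n <- 150
  h <- runif(n, 1, 30)
  cii <- pmin(pmax(round(1 + 7 * h / 30 + rnorm(n, 0, 1)), 1), 8)
  d <- data.frame(age_years = sample(1:100, n, TRUE),
                  dbh_cm = runif(n, 1, 50), height_m = h,
                  cii_ordinal = cii,
                  wi_ppm = 60 + 1.8 * h + 5 * (cii - 1) + rnorm(n, 0, 6))
  sel <- model_selection_aic(d)
  expect_true(all(c("height", "cii") %in% sel$selected))
  expect_equal(sel$table$aic[1], min(sel$table$aic))
  expect_gt(sel$variance_explained, 0.5)

  # duplicated predictor columns give identical AICs; the tie breaks
  # deterministically (equal size -> lexicographic)
  d2 <- d
  d2$dbh_cm <- d$height_m          # diameter duplicates height exactly
  d2$wi_ppm <- 60 + 1.8 * h + rnorm(n, 0, 6)
  sel2 <- model_selection_aic(d2, predictors = c("diameter", "height"))
  expect_identical(sel2$selected, "diameter")

  expect_error(model_selection_aic(d[1:5, ]), "at least 10")
})

test_that("pure-noise response tends to select the intercept-only model", {
  set.seed(26)
  wins <- 0
  for (i in 1:40) {
    n <- 60
    d <- data.frame(age_years = sample(1:100, n, TRUE),
                    dbh_cm = runif(n, 1, 50), height_m = runif(n, 1, 30),
                    cii_ordinal = sample(1:8, n, TRUE),
                    wi_ppm = rnorm(n, 80, 10))
    if (length(model_selection_aic(d)$selected) == 0) wins <- wins + 1
  }
  expect_gt(wins, 14)
})

test_that("mixed model recovers a common slope across species", {
  set.seed(27)
  n_per <- 40
  species <- rep(c("sp1", "sp2", "sp3", "sp4"), each = n_per)
  intercepts <- rep(c(50, 60, 70, 80), each = n_per)
  n <- length(species)
  h <- runif(n, 1, 30)
  d <- data.frame(species = species, age_years = sample(1:100, n, TRUE),
                  dbh_cm = runif(n, 1, 50), height_m = h,
                  cii_ordinal = sample(1:8, n, TRUE),
                  wi_ppm = intercepts + 2 * h + rnorm(n, 0, 4))
  fit <- mixed_effects_all_species(d)
  co <- fit$coefficients
  est <- co$estimate[co$predictor == "height_m"]
  se <- co$se[co$predictor == "height_m"]
  expect_lt(abs(est - 2), 3 * se)
  expect_gt(fit$species_sd, 1)
  expect_true(all(is.finite(co$p_value)))
})

test_that("mixed model degenerates gracefully", {
  set.seed(28)
  n <- 80
  h <- runif(n, 1, 30)
  d <- data.frame(species = rep(c("sp1", "sp2"), each = 40),
                  age_years = sample(1:100, n, TRUE),
                  dbh_cm = runif(n, 1, 50), height_m = h,
                  cii_ordinal = sample(1:8, n, TRUE),
                  wi_ppm = 60 + 2 * h + rnorm(n, 0, 4))
  # no species heterogeneity: variance ~ 0, fixed effects match OLS
  fit <- suppressMessages(mixed_effects_all_species(d))
  ols <- lm(wi_ppm ~ age_years + dbh_cm + height_m + cii_ordinal, data = d)
  expect_lt(fit$species_sd, 1)
  expect_lt(max(abs(fit$coefficients$estimate - unname(coef(ols)[-1]))),
            0.05)

  # single species falls back to fixed effects with a warning
  d$species <- "sp1"
  expect_warning(fit1 <- mixed_effects_all_species(d), "single species")
  expect_equal(fit1$species_sd, 0)
})

test_that("collinear age can take a negative partial effect despite a positive marginal trend", {
  set.seed(29)
  n <- 200
  age <- sample(5:100, n, TRUE)
  h <- 30 * (1 - exp(-0.03 * age)) * exp(rnorm(n, 0, 0.05))
  d <- data.frame(species = rep(c("s1", "s2"), each = 100),
                  age_years = age, dbh_cm = h * 1.5 * exp(rnorm(n, 0, 0.05)),
                  height_m = h,
                  cii_ordinal = pmin(pmax(round(1 + 7 * h / 30), 1), 8),
                  wi_ppm = 60 + 1.8 * h + rnorm(n, 0, 3))
  marginal <- linear_trend(d$age_years, d$wi_ppm, "age")
  expect_gt(marginal$slope, 0)
  fit <- suppressMessages(mixed_effects_all_species(d))
  age_t <- fit$coefficients$t_value[fit$coefficients$predictor == "age_years"]
  height_t <- fit$coefficients$t_value[fit$coefficients$predictor == "height_m"]
  expect_gt(height_t, abs(age_t))
})

test_that("time trends pool per-series slopes with study weights", {
  years <- 1900:1930
  wi_a <- 100 + 0.2 * (years - 1900)   # 20 ppm per 100 yr
  wi_b <- rep(100, length(years))      # flat
  atm <- constant_atmosphere()
  rings <- validate_ring_table(rbind(
    data.frame(tree_id = "A", calendar_year = years,
               ring_index = seq_along(years), block_span_years = 1L,
               d13c_permil = render_d13c(wi_a, 280, -6.4)),
    data.frame(tree_id = "B", calendar_year = years,
               ring_index = seq_along(years), block_span_years = 1L,
               d13c_permil = render_d13c(wi_b, 280, -6.4))))
  tt <- suppressWarnings(time_trend(rings, atm, weights = c(A = 3, B = 1)))
  expect_equal(tt$slope, 15, tolerance = 1e-8)
  # equal weights coincide exactly with the unweighted estimate
  tt_eq <- suppressWarnings(time_trend(rings, atm, weights = c(A = 1, B = 1)))
  tt_un <- suppressWarnings(time_trend(rings, atm))
  expect_identical(tt_eq$slope, tt_un$slope)
  expect_equal(tt_un$slope, 10, tolerance = 1e-8)

  # constant series under a constant atmosphere: zero trend
  flat <- validate_ring_table(
    data.frame(tree_id = "C", calendar_year = years,
               ring_index = seq_along(years), block_span_years = 1L,
               d13c_permil = render_d13c(wi_b, 280, -6.4)))
  tt0 <- suppressWarnings(time_trend(flat, atm))
  expect_equal(tt0$slope, 0, tolerance = 1e-8)
})

test_that("cubic smoothing spline smooths without moving linear series", {
  years <- 1950:1990
  lin <- 10 + 0.5 * (years - 1950)
  out <- spline_smooth_series(years, lin)
  expect_lt(max(abs(out$smoothed - lin)), 1e-6)

  set.seed(30)
  noisy <- lin + rnorm(length(years), 0, 3)
  sm <- spline_smooth_series(years, noisy, spar = 1)
  expect_lt(var(sm$smoothed - lin), var(noisy - lin))

  expect_warning(out3 <- spline_smooth_series(1:3, c(1, 5, 2)), "unsmoothed")
  expect_equal(out3$smoothed, c(1, 5, 2))
})
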