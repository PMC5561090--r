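test_that("atmosphere generator honours its contracts", {
  const <- generate_atmosphere("constant_preindustrial", 1800:1900)
  expect_equal(nrow(const), 101)
  expect_true(all(const$ca_ppm == 280))
  expect_true(all(const$d13c_air_permil == -6.4))

  ramp <- generate_atmosphere("ramp", 1850:2000)
  expect_equal(ramp$ca_ppm[1], 280)
  expect_equal(ramp$ca_ppm[nrow(ramp)], 400)
  expect_true(all(diff(ramp$ca_ppm) > 0))
  expect_true(all(diff(ramp$d13c_air_permil) < 0))

  expect_identical(generate_atmosphere("ramp", 1850:2000),
                   generate_atmosphere("ramp", 1850:2000))
})

test_that("stands are deterministic per seed and follow the Wi model", {
  cfg <- stand_config(n_trees = 50, seed = 101)
  s1 <- generate_stand(cfg)
  s2 <- generate_stand(cfg)
  expect_identical(s1, s2)
  s3 <- generate_stand(stand_config(n_trees = 50, seed = 102))
  expect_false(identical(s1$trees$height_m, s3$trees$height_m))

  # with sigma = 0 and no light effect, true Wi is exactly linear in height
  cfg0 <- stand_config(n_trees = 50, sigma = 0, beta_light = 0, seed = 103)
  s0 <- generate_stand(cfg0)
  expect_equal(s0$truth$true_wi_ppm,
               cfg0$beta0 + cfg0$beta_height * s0$truth$height_m / 10,
               tolerance = 1e-12)

  # residual mean obeys the law of large numbers
  cfgN <- stand_config(n_trees = 10000, seed = 104)
  sN <- generate_stand(cfgN)
  eps <- sN$truth$true_wi_ppm -
    (cfgN$beta0 + cfgN$beta_height * sN$truth$height_m / 10 +
       cfgN$beta_light * (sN$truth$cii_ordinal - 1))
  expect_lt(abs(mean(eps)), 3 * cfgN$sigma / sqrt(10000))
})

test_that("rendered d13C inverts the analysis chain exactly", {
  # Wi of 0+ maps to Delta = b: d13C = (-6.4 - 27) / 1.027
  d_limit <- invert_discrimination(27, -6.4)
  expect_equal(d_limit, (-6.4 - 27) / 1.027, tolerance = 1e-12)
  expect_equal(render_d13c(1e-12, 280, -6.4), d_limit, tolerance = 1e-9)

  # worked example round trip
  wi <- (280 - 280 * (17.6 / 0.976 - 4.4) / 22.6) / 1.6
  expect_equal(render_d13c(wi, 280, -6.4), -24, tolerance = 1e-10)

  set.seed(105)
  wis <- runif(300, 5, 170)
  back <- gas_exchange_state(render_d13c(wis, 280, -6.4), 1800,
                             constant_atmosphere())
  expect_equal(back$wi_ppm, wis, tolerance = 1e-9)
  expect_error(render_d13c(200, 280, -6.4), "physical range")
})

test_that("noise-free closed loop recovers the injected coefficients", {
  cfg <- stand_config(n_trees = 60, sigma = 0, beta_light = 0, cii_sd = 0,
                      seed = 106)
  sim <- simulate_size_stratified_sample(cfg)
  wt <- run_wi(sim$trees, sim$atmos)
  expect_equal(wt$wi_ppm, sim$truth$true_wi_ppm, tolerance = 1e-9)
  fit <- suppressWarnings(linear_trend(wt$height_m, wt$wi_ppm, "height"))
  expect_equal(fit$slope, cfg$beta_height, tolerance = 1e-8)

  # with a light effect: multiple regression recovers both coefficients
  cfg2 <- stand_config(n_trees = 80, sigma = 0, seed = 107)
  sim2 <- simulate_size_stratified_sample(cfg2)
  wt2 <- run_wi(sim2$trees, sim2$atmos)
  co <- coef(lm(wi_ppm ~ I(height_m / 10) + I(cii_ordinal - 1), data = wt2))
  expect_equal(unname(co[2]), cfg2$beta_height, tolerance = 1e-8)
  expect_equal(unname(co[3]), cfg2$beta_light, tolerance = 1e-8)

  # same loop through the canopy profile, analysed with the same profile
  prof <- canopy_profile("tropical")
  cfg3 <- stand_config(n_trees = 40, sigma = 0, profile = prof,
                       forest_type = "tropical", seed = 108)
  sim3 <- simulate_size_stratified_sample(cfg3)
  wt3 <- run_wi(sim3$trees, sim3$atmos, correct = TRUE,
                profiles = list(tropical = prof))
  expect_equal(wt3$wi_ppm, sim3$truth$true_wi_ppm, tolerance = 1e-9)
})

test_that("size-stratified outputs are deterministic and CSV round-trippable", {
  cfg <- stand_config(n_trees = 30, seed = 109)
  sim1 <- simulate_size_stratified_sample(cfg)
  sim2 <- simulate_size_stratified_sample(cfg)
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_tree_table(sim1$trees, f1)
  write_tree_table(sim2$trees, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(nrow(read_tree_table(f1)), nrow(sim1$trees))
})

test_that("dominant-tree series embody the developmental history", {
  # no developmental effects: flat Wi series, zero time trend
  cfg0 <- stand_config(n_trees = 30, sigma = 0, beta_height = 0,
                       beta_light = 0, seed = 110)
  dom0 <- simulate_dominant_tree_series(cfg0, n_dominant = 3)
  tt0 <- suppressWarnings(time_trend(dom0$rings, dom0$atmos))
  expect_equal(tt0$slope, 0, tolerance = 1e-8)

  # developmental effects on: per-year truth follows the growth curve
  cfg <- stand_config(n_trees = 30, sigma = 0, beta_light = 0, cii_sd = 0,
                      height_noise_sdlog = 0, seed = 111)
  dom <- simulate_dominant_tree_series(cfg, n_dominant = 2)
  one <- dom$truth[dom$truth$tree_id == dom$truth$tree_id[1], ]
  h_exp <- cfg$hmax_m * (1 - exp(-cfg$growth_rate * one$ring_index))
  expect_equal(one$height_m, h_exp, tolerance = 1e-12)
  expect_true(all(diff(one$true_wi_ppm) > 0))

  # determinism
  dom_b <- simulate_dominant_tree_series(cfg, n_dominant = 2)
  expect_identical(dom$rings, dom_b$rings)
})
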