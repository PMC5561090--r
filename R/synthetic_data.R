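# Synthetic stands with known ground truth. The generator emulates a
# size-stratified field campaign: trees of all sizes sampled in one year, a
# true Wi that increases with height and crown illumination, and optional
# below-canopy source-air gradients — so the whole pipeline is testable
# without field data, and the central confound (a developmental trend read
# as a time trend) can be demonstrated quantitatively.

# Truncated Gaussian draw (rejection sampling). Noise terms are truncated so
# that every simulated Wi stays strictly inside the physically admissible
# range (0, ca/1.6); symmetric truncation keeps slope recovery unbiased.
rnorm_trunc <- function(n, sd, trunc = 3) {
  if (sd == 0) return(rep(0, n))
  x <- stats::rnorm(n, 0, sd)
  bad <- abs(x) > trunc * sd
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), 0, sd)
    bad <- abs(x) > trunc * sd
  }
  x
}

#' Configuration of a synthetic stand
#'
#' Collects every knob of the generator. Heights follow a monomolecular
#' (von Bertalanffy) growth curve `H(t) = hmax_m * (1 - exp(-growth_rate *
#' t))` with multiplicative lognormal noise between trees; crown
#' illumination is a monotone stochastic function of height relative to the
#' canopy top (latent score `1 + 7 * min(H / canopy_height, 1)` plus
#' Gaussian noise, rounded to the ordinal classes 1..8); and the true
#' intrinsic water-use efficiency of each tree is
#' `beta0 + beta_height * H / 10 + beta_light * (CII - 1) + N(0, sigma)`.
#'
#' The defaults describe a closed temperate broadleaf stand: 150 trees with
#' ages even across 1-100 yr, a 30 m canopy reached with mid-life height
#' growth near 0.3 m/yr, a height effect of 18 ppm per 10 m and a light
#' effect of 5 ppm per illumination step on top of a 40 ppm shaded-seedling
#' baseline, with 8 ppm residual spread — magnitudes representative of the
#' strong developmental Wi gradients reported for temperate and tropical
#' broadleaf species, and jointly chosen so that every simulated Wi lies
#' inside the physical range (0, ca/1.6). Noise terms are symmetric
#' truncated Gaussians (residual at 3 sigma, log height multiplier at
#' 2.5 sigma) for the same reason.
#'
#' @param n_trees Number of trees.
#' @param age_range Two-element integer range of tree ages (yr).
#' @param hmax_m Asymptotic height of the growth curve (m).
#' @param growth_rate Growth-curve rate constant (1/yr).
#' @param height_noise_sdlog SD of the per-tree lognormal height multiplier
#'   (0 = deterministic growth).
#' @param canopy_height_m Height of the canopy top used by the light model.
#' @param cii_sd SD of the latent noise of the crown illumination model.
#' @param beta0 Baseline Wi (ppm).
#' @param beta_height Height effect on Wi, ppm per 10 m.
#' @param beta_light Light effect on Wi, ppm per CII step.
#' @param sigma Residual SD of true Wi (ppm).
#' @param forest_type `"temperate"`, `"tropical"` or `"open"`.
#' @param atmosphere `"constant_preindustrial"` (280 ppm, -6.4 permil at
#'   every year) or `"ramp"` (monotone CO2 rise with matching delta13C
#'   decline).
#' @param ramp_co2 Two-element CO2 endpoints for ramp mode (ppm).
#' @param ramp_d13c Two-element delta13C endpoints for ramp mode (permil).
#' @param sampling_year Calendar year of the (single) field campaign.
#' @param profile Either `NULL` (no below-canopy gradient) or a
#'   [canopy_profile()] used when rendering ring isotopes.
#' @param open_grown If TRUE, all trees get full crown exposure (CII 8) at
#'   every age, emulating an open planting.
#' @param species,site_id Labels written into the tree table.
#' @param seed Integer seed; every stochastic draw of the generator flows
#'   from it.
#' @return A list of class `stand_config`.
#' @export
stand_config <- function(n_trees = 150,
                         age_range = c(1, 100),
                         hmax_m = 30,
                         growth_rate = 0.02,
                         height_noise_sdlog = 0.12,
                         canopy_height_m = hmax_m,
                         cii_sd = 1.0,
                         beta0 = 40,
                         beta_height = 18,
                         beta_light = 5,
                         sigma = 8,
                         forest_type = "temperate",
                         atmosphere = c("constant_preindustrial", "ramp"),
                         ramp_co2 = c(280, 400),
                         ramp_d13c = c(-6.4, -8.5),
                         sampling_year = 1900,
                         profile = NULL,
                         open_grown = FALSE,
                         species = "synthetic_sp",
                         site_id = "synthetic_site",
                         seed = 20170818) {
  atmosphere <- match.arg(atmosphere)
  stopifnot(n_trees >= 1, hmax_m > 0, growth_rate > 0, sigma >= 0,
            length(age_range) == 2, age_range[1] >= 1,
            age_range[2] >= age_range[1])
  if (!is.null(profile) && !inherits(profile, "canopy_profile"))
    stop("profile must be NULL or a 'canopy_profile'")
  structure(as.list(environment()), class = "stand_config")
}

#' Generate an atmospheric record for a scenario
#'
#' Constant mode yields the fixed pre-industrial atmosphere (280 ppm CO2,
#' delta13C of -6.4 permil) at every year of the span; ramp mode yields a
#' linear, monotone CO2 increase with a matching monotone delta13C decline
#' between configurable endpoints (a stylised industrial-era trajectory for
#' scenario testing, not a historical record).
#'
#' @param mode `"constant_preindustrial"` or `"ramp"`.
#' @param years Integer vector of calendar years (will be sorted, unique).
#' @param co2_endpoints,d13c_endpoints Ramp endpoints.
#' @return An `atmos` object tabulated at each year.
#' @export
generate_atmosphere <- function(mode = c("constant_preindustrial", "ramp"),
                                years,
                                co2_endpoints = c(280, 400),
                                d13c_endpoints = c(-6.4, -8.5)) {
  mode <- match.arg(mode)
  years <- sort(unique(as.integer(years)))
  if (length(years) < 1) stop("span must contain at least one year")
  if (mode == "constant_preindustrial") {
    atmosphere_record(years, rep(280, length(years)),
                      rep(-6.4, length(years)))
  } else {
    frac <- if (length(years) == 1) 0 else
      (years - years[1]) / (years[length(years)] - years[1])
    atmosphere_record(
      years,
      co2_endpoints[1] + frac * (co2_endpoints[2] - co2_endpoints[1]),
      d13c_endpoints[1] + frac * (d13c_endpoints[2] - d13c_endpoints[1]))
  }
}

# Deterministic pieces of the generator, shared between the stand snapshot
# and the dominant-tree histories.
growth_height <- function(age, config) {
  config$hmax_m * (1 - exp(-config$growth_rate * age))
}

cii_ordinal_from_height <- function(height, config, latent_noise = 0) {
  if (config$open_grown) return(rep(8L, length(height)))
  latent <- 1 + 7 * pmin(height / config$canopy_height_m, 1) + latent_noise
  pmin(pmax(as.integer(round(latent)), 1L), 8L)
}

true_wi_model <- function(height, cii_ordinal, config, eps = 0) {
  config$beta0 + config$beta_height * height / 10 +
    config$beta_light * (cii_ordinal - 1) + eps
}

#' Generate a size-stratified stand with hidden truth
#'
#' Draws tree ages uniformly over the configured range (emulating an even
#' sample across size classes), heights from the growth curve with
#' per-tree lognormal noise, crown illumination from the monotone light
#' model and true Wi from the linear height + light model. No isotope
#' values are rendered yet; see [simulate_size_stratified_sample()].
#'
#' @param config A [stand_config()].
#' @return A list with `trees` (data frame: tree_id, species, site_id,
#'   forest_type, sampling_year, age_years, dbh_cm, height_m, cii_class,
#'   cii_ordinal) and `truth` (data frame: tree_id, height_m, cii_ordinal,
#'   true_wi_ppm, height_multiplier, cii_latent_noise).
#' @export
generate_stand <- function(config) {
  stopifnot(inherits(config, "stand_config"))
  set.seed(config$seed)
  n <- config$n_trees
  ages <- if (config$age_range[1] == config$age_range[2])
    rep(config$age_range[1], n) else
    sample(seq(config$age_range[1], config$age_range[2]), n, replace = TRUE)
  mult <- exp(rnorm_trunc(n, config$height_noise_sdlog, trunc = 2.5))
  height <- growth_height(ages, config) * mult
  latent_noise <- stats::rnorm(n, 0, config$cii_sd)
  cii_ord <- cii_ordinal_from_height(height, config, latent_noise)
  eps <- rnorm_trunc(n, config$sigma)
  wi_true <- true_wi_model(height, cii_ord, config, eps)
  # allometric diameter, recorded only for corable trees (height >= 1.3 m)
  dbh <- 0.9 * height^1.25 * exp(stats::rnorm(n, 0, 0.08))
  dbh[height < 1.3] <- NA_real_
  trees <- data.frame(
    tree_id = sprintf("T%03d", seq_len(n)),
    species = config$species,
    site_id = config$site_id,
    forest_type = config$forest_type,
    sampling_year = config$sampling_year,
    age_years = as.integer(ages),
    dbh_cm = dbh,
    height_m = height,
    cii_class = CII_CLASSES[cii_ord],
    cii_ordinal = cii_ord,
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    tree_id = trees$tree_id,
    height_m = height,
    cii_ordinal = cii_ord,
    true_wi_ppm = wi_true,
    height_multiplier = mult,
    cii_latent_noise = latent_noise,
    stringsAsFactors = FALSE
  )
  list(trees = trees, truth = truth)
}

#' Render the ring delta13C a tree with known Wi would record
#'
#' Inverse of the analysis chain: the prescribed Wi is converted to the
#' discrimination `Delta = b - 1.6 * Wi * (b - a) / ca` and then to the
#' plant delta13C via the inverse discrimination formula, using the source
#' air (ca, d13c_air) the tree actually assimilated. Analysing the result
#' with the same source-air assumptions recovers Wi exactly.
#'
#' @param wi_ppm True intrinsic water-use efficiency, ppm; must lie in the
#'   physical range (0, ca / 1.6).
#' @param ca_ppm Source-air CO2 at the point of uptake, ppm.
#' @param d13c_air_permil Source-air delta13C, permil.
#' @param constants [isotope_constants()].
#' @return Plant delta13C, permil vs V-PDB. Vectorised.
#' @export
render_d13c <- function(wi_ppm, ca_ppm, d13c_air_permil,
                        constants = isotope_constants()) {
  r <- constants$diffusivity_ratio
  a <- constants$a_permil
  b <- constants$b_permil
  if (any(wi_ppm <= 0 | wi_ppm >= ca_ppm / r))
    stop("wi_ppm outside the physical range (0, ca / 1.6)")
  big_delta <- b - r * wi_ppm * (b - a) / ca_ppm
  invert_discrimination(big_delta, d13c_air_permil)
}

# Source air seen by a crown: above-canopy air, or the below-canopy mixture
# at 0.9 x tree height when a profile is active for a closed forest.
source_air_for <- function(height_m, config, ca_above, d13c_above) {
  if (is.null(config$profile) || config$forest_type == "open") {
    data.frame(ca_ppm = ca_above, d13c_air_permil = d13c_above)
  } else {
    below_canopy_air(effective_uptake_height(height_m), config$profile,
                     ca_above, d13c_above)
  }
}

#' Simulate a size-stratified isotope sample
#'
#' Full emulation of the field design: generates a stand, renders one bulk
#' outer-ring delta13C per tree at the common sampling year (through the
#' below-canopy profile when configured) and returns a validated tree table
#' together with the hidden truth. Everything is deterministic per seed.
#'
#' @param config A [stand_config()].
#' @return List with `trees` (a `tree_table` including `d13c_outer_permil`),
#'   `truth`, `atmos` (the scenario atmosphere) and `config`.
#' @export
simulate_size_stratified_sample <- function(config) {
  stopifnot(inherits(config, "stand_config"))
  span <- seq(config$sampling_year - config$age_range[2],
              config$sampling_year)
  atmos <- generate_atmosphere(config$atmosphere, span, config$ramp_co2,
                               config$ramp_d13c)
  stand <- generate_stand(config)
  above <- atmos_lookup(rep(config$sampling_year, nrow(stand$trees)), atmos)
  air <- source_air_for(stand$trees$height_m, config, above$ca_ppm,
                        above$d13c_air_permil)
  stand$trees$d13c_outer_permil <- render_d13c(stand$truth$true_wi_ppm,
                                               air$ca_ppm,
                                               air$d13c_air_permil)
  trees <- suppressWarnings(validate_tree_table(stand$trees,
                                                what = "synthetic stand"))
  truth <- stand$truth[stand$truth$tree_id %in% trees$tree_id, ]
  list(trees = trees, truth = truth, atmos = atmos, config = config)
}

#' Simulate dominant-tree ring series (the classical chronology material)
#'
#' Reconstructs the full life history of the largest/oldest trees of a
#' synthetic stand: per-year height from the growth curve (each tree keeps
#' its own height multiplier), a stepwise-monotone crown illumination
#' trajectory, per-year true Wi, and the rendered annual ring delta13C
#' against the year-matched atmosphere. Under a constant atmosphere any
#' apparent time trend in the analysed series is purely developmental —
#' exactly the confound that backward-looking chronologies inherit.
#'
#' @param config A [stand_config()].
#' @param n_dominant Number of dominant (oldest) trees to reconstruct.
#' @return List with `rings` (a `ring_table` of annual observations),
#'   `truth` (per tree-year: height, CII, true Wi), `trees` (the dominant
#'   subset of the stand table), `atmos`, `config`.
#' @export
simulate_dominant_tree_series <- function(config, n_dominant = 5) {
  stopifnot(inherits(config, "stand_config"))
  span <- seq(config$sampling_year - config$age_range[2],
              config$sampling_year)
  atmos <- generate_atmosphere(config$atmosphere, span, config$ramp_co2,
                               config$ramp_d13c)
  stand <- generate_stand(config)
  ord <- order(stand$trees$age_years, stand$trees$height_m,
               decreasing = TRUE)
  pick <- utils::head(ord, n_dominant)
  rings <- list()
  truths <- list()
  for (i in pick) {
    tree <- stand$trees[i, ]
    tr <- stand$truth[i, ]
    t_seq <- seq_len(tree$age_years)
    years <- tree$sampling_year - tree$age_years + t_seq
    h_t <- growth_height(t_seq, config) * tr$height_multiplier
    cii_t <- cii_ordinal_from_height(h_t, config, tr$cii_latent_noise)
    eps_t <- rnorm_trunc(length(t_seq), config$sigma)
    wi_t <- true_wi_model(h_t, cii_t, config, eps_t)
    above <- atmos_lookup(years, atmos)
    air <- source_air_for(h_t, config, above$ca_ppm, above$d13c_air_permil)
    d13c_t <- render_d13c(wi_t, air$ca_ppm, air$d13c_air_permil)
    rings[[tree$tree_id]] <- data.frame(
      tree_id = tree$tree_id, calendar_year = years, ring_index = t_seq,
      block_span_years = 1L, d13c_permil = d13c_t)
    truths[[tree$tree_id]] <- data.frame(
      tree_id = tree$tree_id, calendar_year = years, ring_index = t_seq,
      height_m = h_t, cii_ordinal = cii_t, true_wi_ppm = wi_t)
  }
  rings <- validate_ring_table(do.call(rbind, rings),
                               what = "synthetic dominant-tree series")
  list(rings = rings, truth = do.call(rbind, truths),
       trees = stand$trees[pick, ], atmos = atmos, config = config)
}
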