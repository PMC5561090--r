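# Below-canopy source air: soil-respired CO2 raises ca and lowers d13C_air
# near the forest floor; both effects decay exponentially with height.

#' Below-canopy source-air profile parameters
#'
#' Describes the vertical gradient of CO2 and its delta13C beneath a forest
#' canopy caused by soil respiration. The CO2 excess over above-canopy air
#' decays as a negative exponential of height,
#' `excess(h) = co2_excess_ground_ppm * exp(-h / e_folding_height_m)`, and
#' the isotopic composition follows from a two-member (Keeling-type) mass
#' balance between above-canopy air and soil-respired CO2.
#'
#' The default amplitudes (temperate: 25 ppm ground excess, 2 m e-folding
#' height; tropical: 40 ppm, 3 m — tropical gradients being somewhat
#' stronger; respired delta13C of -28 permil) are package defaults
#' representative of published daytime forest profiles, configurable per
#' forest type.
#'
#' @param forest_type `"temperate"` or `"tropical"`.
#' @param co2_excess_ground_ppm CO2 excess at the forest floor relative to
#'   above-canopy air, ppm (>= 0).
#' @param e_folding_height_m Height over which the excess decays by 1/e,
#'   m (> 0).
#' @param d13c_respired_permil delta13C of soil-respired CO2, permil.
#' @return An object of class `canopy_profile`.
#' @export
canopy_profile <- function(forest_type = c("temperate", "tropical"),
                           co2_excess_ground_ppm = NULL,
                           e_folding_height_m = NULL,
                           d13c_respired_permil = -28) {
  forest_type <- match.arg(forest_type)
  defaults <- list(temperate = c(excess = 25, efold = 2),
                   tropical = c(excess = 40, efold = 3))[[forest_type]]
  if (is.null(co2_excess_ground_ppm))
    co2_excess_ground_ppm <- unname(defaults["excess"])
  if (is.null(e_folding_height_m))
    e_folding_height_m <- unname(defaults["efold"])
  if (co2_excess_ground_ppm < 0)
    stop("co2_excess_ground_ppm must be non-negative")
  if (e_folding_height_m <= 0)
    stop("e_folding_height_m must be positive")
  structure(list(forest_type = forest_type,
                 co2_excess_ground_ppm = co2_excess_ground_ppm,
                 e_folding_height_m = e_folding_height_m,
                 d13c_respired_permil = d13c_respired_permil),
            class = "canopy_profile")
}

#' Effective CO2 uptake height of a tree crown
#'
#' Average CO2 uptake by a crown occurs slightly below the tree top; it is
#' taken as 0.9 times total tree height.
#'
#' @param total_height_m Total tree height, m (> 0). Vectorised.
#' @return Effective uptake height in m.
#' @export
effective_uptake_height <- function(total_height_m) {
  if (any(total_height_m <= 0)) stop("total_height_m must be positive")
  0.9 * total_height_m
}

#' Source air at a height below the canopy
#'
#' Mixes above-canopy air with soil-respired CO2. The CO2 excess decays
#' exponentially with height; the delta13C of the mixture is the exact
#' two-member mass balance
#' `(ca_above * d13c_above + excess(h) * d13c_respired) / ca(h)`, so the
#' isotopic and CO2 profiles are internally consistent by construction and
#' `d13c_air(h) <= d13c_above` whenever the respired end member is more
#' depleted than the free atmosphere.
#'
#' @param height_m Height(s) above the forest floor, m (>= 0). Vectorised.
#' @param profile A [canopy_profile()].
#' @param ca_above Above-canopy CO2, ppm (> 0).
#' @param d13c_air_above Above-canopy delta13C of CO2, permil.
#' @return Data frame with columns `ca_ppm` and `d13c_air_permil`.
#' @examples
#' p <- canopy_profile("temperate", 30, 2)
#' below_canopy_air(0, p, 400, -8)
#' @export
below_canopy_air <- function(height_m, profile, ca_above, d13c_air_above) {
  if (!inherits(profile, "canopy_profile"))
    stop("profile must be a 'canopy_profile' object")
  if (any(ca_above <= 0)) stop("ca_above must be positive")
  if (any(height_m < 0)) stop("height_m must be non-negative")
  excess <- profile$co2_excess_ground_ppm *
    exp(-height_m / profile$e_folding_height_m)
  ca_h <- ca_above + excess
  d13c_h <- (ca_above * d13c_air_above +
               excess * profile$d13c_respired_permil) / ca_h
  data.frame(ca_ppm = ca_h, d13c_air_permil = d13c_h)
}

#' Gas exchange corrected for below-canopy source air
#'
#' Evaluates the full isotope chain for the trees of a tree table using the
#' source air each crown actually saw: `(ca, d13c_air)` from
#' [below_canopy_air()] at [effective_uptake_height()] of the tree. Trees in
#' open stands (`forest_type == "open"`) bypass the correction and use
#' above-canopy air directly.
#'
#' @param trees A `tree_table` (see [read_tree_table()]); one state per row
#'   is computed from `d13c_outer_permil` at `sampling_year`.
#' @param atmos Above-canopy atmospheric record (`atmos` object).
#' @param profiles Named list of [canopy_profile()] objects keyed by forest
#'   type, e.g. `list(temperate = canopy_profile("temperate"))`. Defaults to
#'   the package default profiles for both closed-forest types.
#' @param constants [isotope_constants()].
#' @return A `gas_exchange_state` data frame with one row per tree, plus a
#'   `tree_id` column.
#' @export
corrected_gas_exchange <- function(trees, atmos,
                                   profiles = default_canopy_profiles(),
                                   constants = isotope_constants()) {
  above <- atmos_lookup(trees$sampling_year, atmos)
  ca <- above$ca_ppm
  d13c_air <- above$d13c_air_permil
  closed <- trees$forest_type != "open"
  if (any(closed)) {
    types <- unique(trees$forest_type[closed])
    missing <- setdiff(types, names(profiles))
    if (length(missing) > 0)
      stop(sprintf("no canopy profile configured for forest type(s): %s",
                   paste(missing, collapse = ", ")))
    for (ft in types) {
      sel <- closed & trees$forest_type == ft
      air <- below_canopy_air(effective_uptake_height(trees$height_m[sel]),
                              profiles[[ft]], ca[sel], d13c_air[sel])
      ca[sel] <- air$ca_ppm
      d13c_air[sel] <- air$d13c_air_permil
    }
  }
  out <- gas_exchange_state_at(trees$d13c_outer_permil, trees$sampling_year,
                               ca, d13c_air, constants)
  out <- cbind(tree_id = trees$tree_id, out)
  class(out) <- c("gas_exchange_state", "data.frame")
  out
}

#' Default below-canopy profiles for both closed forest types
#'
#' @return Named list with `temperate` and `tropical` [canopy_profile()]s.
#' @export
default_canopy_profiles <- function() {
  list(temperate = canopy_profile("temperate"),
       tropical = canopy_profile("tropical"))
}

#' Relative impact of the source-air correction on a trend
#'
#' Percent by which the corrected developmental slope falls short of the
#' uncorrected one: `100 * (uncorrected - corrected) / uncorrected`.
#' Positive values mean the correction lowered the inferred trend.
#'
#' @param slope_uncorrected Slope estimated with above-canopy source air.
#' @param slope_corrected Slope estimated with below-canopy source air.
#' @return Impact in percent.
#' @export
correction_impact <- function(slope_uncorrected, slope_corrected) {
  if (any(slope_uncorrected == 0))
    stop("correction impact is undefined for a zero uncorrected slope")
  100 * (slope_uncorrected - slope_corrected) / slope_uncorrected
}
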