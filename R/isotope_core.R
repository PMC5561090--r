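# Farquhar-model chain: ring d13C -> discrimination -> ci -> Wi.

#' Isotope fractionation constants
#'
#' Constants of the simple (two-endmember) Farquhar discrimination model used
#' throughout the package: `a`, the fractionation caused by the slower
#' diffusion of 13CO2 relative to 12CO2 through the stomata; `b`, the net
#' fractionation by Rubisco carboxylation; and the ratio of molecular
#' diffusivities of water vapour and CO2 in air, which converts stomatal
#' conductance for CO2 into conductance for water vapour. Mesophyll
#' conductance and post-photosynthetic fractionation are deliberately not
#' modelled; `a` and `b` are exposed so that sensitivity of downstream trends
#' to the assumed endpoints can be explored.
#'
#' @param a_permil Diffusion fractionation in permil. Default 4.4.
#' @param b_permil Rubisco fractionation in permil. Default 27.
#' @param diffusivity_ratio Ratio of H2O to CO2 diffusivity. Default 1.6.
#' @return An object of class `isotope_constants` (a named list).
#' @examples
#' isotope_constants()
#' @export
isotope_constants <- function(a_permil = 4.4, b_permil = 27,
                              diffusivity_ratio = 1.6) {
  stopifnot(is.numeric(a_permil), is.numeric(b_permil),
            is.numeric(diffusivity_ratio))
  if (!(b_permil > a_permil && a_permil > 0))
    stop("isotope constants must satisfy b > a > 0")
  if (diffusivity_ratio <= 1)
    stop("diffusivity_ratio must exceed 1")
  structure(list(a_permil = a_permil, b_permil = b_permil,
                 diffusivity_ratio = diffusivity_ratio),
            class = "isotope_constants")
}

#' Carbon isotope ratio in delta notation
#'
#' Converts 13C/12C abundance ratios to the delta notation (permil versus
#' V-PDB): `(r_sample / r_standard - 1) * 1000`.
#'
#' @param r_sample Abundance ratio 13C/12C of the sample (> 0). Vectorised.
#' @param r_standard Abundance ratio of the standard (V-PDB, > 0).
#' @return delta13C in permil vs V-PDB.
#' @examples
#' delta13c_from_ratio(0.97, 1)   # -30 permil
#' @export
delta13c_from_ratio <- function(r_sample, r_standard) {
  if (any(r_sample <= 0) || any(r_standard <= 0))
    stop("abundance ratios must be positive")
  (r_sample / r_standard - 1) * 1000
}

#' Plant-to-air carbon isotope discrimination
#'
#' Computes discrimination Delta13C from the isotopic composition of the
#' plant material and of atmospheric CO2:
#' `(d13c_air - d13c_plant) / (1 + d13c_plant / 1000)`.
#'
#' @param d13c_plant Plant (ring cellulose) delta13C, permil vs V-PDB.
#' @param d13c_air Atmospheric CO2 delta13C, permil vs V-PDB.
#' @return Discrimination in permil. Vectorised.
#' @examples
#' discrimination(-25, -8)   # 17/0.975
#' @export
discrimination <- function(d13c_plant, d13c_air) {
  denom <- 1 + d13c_plant / 1000
  if (any(denom <= 0))
    stop("1 + d13c_plant/1000 must be positive")
  (d13c_air - d13c_plant) / denom
}

#' Invert discrimination back to plant delta13C
#'
#' Exact algebraic inverse of [discrimination()]: given a discrimination and
#' the source-air delta13C, returns the plant delta13C that would produce it.
#' Used by the synthetic-data generator to render ring isotope ratios from a
#' prescribed intrinsic water-use efficiency.
#'
#' @param big_delta Discrimination Delta13C, permil.
#' @param d13c_air Source-air delta13C, permil.
#' @return Plant delta13C in permil. Vectorised.
#' @export
invert_discrimination <- function(big_delta, d13c_air) {
  denom <- 1 + big_delta / 1000
  if (any(denom <= 0))
    stop("1 + big_delta/1000 must be positive")
  (d13c_air - big_delta) / denom
}

#' Leaf intercellular CO2 from discrimination
#'
#' Linear form of the Farquhar model: `ci = ca * (Delta - a) / (b - a)`.
#' Values of Delta outside the open interval (a, b) produce ci outside
#' (0, ca); such values are returned as-is (never clipped) so that callers
#' can flag physically implausible states instead of silently biasing trends.
#'
#' @param big_delta Discrimination, permil.
#' @param ca Atmospheric CO2 mole fraction, ppm (> 0).
#' @param constants An [isotope_constants()] object.
#' @return ci in ppm. Vectorised over `big_delta` and `ca`.
#' @export
ci_from_discrimination <- function(big_delta, ca,
                                   constants = isotope_constants()) {
  if (any(ca <= 0)) stop("ca must be positive")
  a <- constants$a_permil
  b <- constants$b_permil
  ca * (big_delta - a) / (b - a)
}

#' Intrinsic water-use efficiency from discrimination
#'
#' Wi is the ratio of assimilation to stomatal conductance for water vapour,
#' `A / gw = (ca - ci) / 1.6`, expressed through discrimination as
#' `ca * (b - Delta) / (1.6 * (b - a))`. Units are ppm (the mole fraction,
#' umol mol^-1).
#'
#' @inheritParams ci_from_discrimination
#' @return Wi in ppm. Vectorised.
#' @examples
#' # pre-industrial source air, ring d13C of -24 permil
#' D <- discrimination(-24, -6.4)
#' wi_from_discrimination(D, 280)
#' @export
wi_from_discrimination <- function(big_delta, ca,
                                   constants = isotope_constants()) {
  if (any(ca <= 0)) stop("ca must be positive")
  a <- constants$a_permil
  b <- constants$b_permil
  ca * (b - big_delta) / (constants$diffusivity_ratio * (b - a))
}

#' Full per-observation gas-exchange state
#'
#' Chains the formula sequence from ring delta13C to discrimination, ci,
#' ci/ca, ca - ci and Wi against the source air of a given calendar year.
#' Discrimination outside the (a, b) interval yields ci and Wi outside their
#' physical ranges; the state is then flagged (`out_of_range = TRUE`) rather
#' than clipped, and flagged states are excluded from trend fits by default.
#'
#' @param d13c_plant Ring delta13C, permil vs V-PDB. Vectorised.
#' @param year Calendar year(s) of ring formation (recycled against
#'   `d13c_plant`).
#' @param atmos An atmospheric record, see [atmosphere_record()] /
#'   [constant_atmosphere()].
#' @param constants An [isotope_constants()] object.
#' @return A data frame of class `gas_exchange_state` with columns `year`,
#'   `ca_ppm`, `d13c_air_permil`, `d13c_plant_permil`, `big_delta_permil`,
#'   `ci_ppm`, `ci_over_ca`, `ca_minus_ci_ppm`, `wi_ppm`, `out_of_range`.
#' @examples
#' gas_exchange_state(-24, 1800, constant_atmosphere())
#' @export
gas_exchange_state <- function(d13c_plant, year, atmos,
                               constants = isotope_constants()) {
  n <- max(length(d13c_plant), length(year))
  d13c_plant <- rep_len(d13c_plant, n)
  year <- rep_len(year, n)
  air <- atmos_lookup(year, atmos)
  gas_exchange_state_at(d13c_plant, year, air$ca_ppm, air$d13c_air_permil,
                        constants)
}

# Shared constructor used by both the plain and the canopy-corrected paths,
# once the source air (ca, d13c_air) at the point of uptake is known.
gas_exchange_state_at <- function(d13c_plant, year, ca, d13c_air,
                                  constants = isotope_constants()) {
  big_delta <- discrimination(d13c_plant, d13c_air)
  ci <- ci_from_discrimination(big_delta, ca, constants)
  wi <- wi_from_discrimination(big_delta, ca, constants)
  out <- data.frame(
    year = year,
    ca_ppm = ca,
    d13c_air_permil = d13c_air,
    d13c_plant_permil = d13c_plant,
    big_delta_permil = big_delta,
    ci_ppm = ci,
    ci_over_ca = ci / ca,
    ca_minus_ci_ppm = ca - ci,
    wi_ppm = wi,
    out_of_range = big_delta <= constants$a_permil |
      big_delta >= constants$b_permil
  )
  class(out) <- c("gas_exchange_state", "data.frame")
  out
}

#' Atmospheric record of CO2 and delta13C
#'
#' Builds a validated calendar series of atmospheric CO2 mole fraction and
#' CO2 delta13C. Years must be strictly increasing. Lookups between
#' tabulated years are linearly interpolated; extrapolation beyond the span
#' is refused.
#'
#' @param year Integer calendar years (AD), strictly increasing.
#' @param ca_ppm Atmospheric CO2, ppm (> 0).
#' @param d13c_air_permil delta13C of atmospheric CO2, permil vs V-PDB.
#' @return A data frame of class `atmos` with attribute `mode = "record"`.
#' @seealso [constant_atmosphere()] for the fixed pre-industrial atmosphere.
#' @export
atmosphere_record <- function(year, ca_ppm, d13c_air_permil) {
  stopifnot(length(year) == length(ca_ppm),
            length(year) == length(d13c_air_permil))
  if (length(year) < 1) stop("atmospheric record must have at least one year")
  if (is.unsorted(year, strictly = TRUE))
    stop("years must be strictly increasing with no duplicates")
  if (any(ca_ppm <= 0)) stop("ca_ppm must be positive at every year")
  out <- data.frame(year = as.integer(year), ca_ppm = ca_ppm,
                    d13c_air_permil = d13c_air_permil)
  attr(out, "mode") <- "record"
  class(out) <- c("atmos", "data.frame")
  out
}

#' Constant pre-industrial atmosphere
#'
#' A degenerate atmospheric record that returns the same CO2 mole fraction
#' and delta13C for every year. The defaults (280 ppm, -6.4 permil) are the
#' conventional pre-industrial values used when analysing sub-fossil wood
#' whose rings all formed before the industrial-era CO2 rise and Suess
#' decline of atmospheric delta13C.
#'
#' @param ca_ppm CO2 mole fraction, ppm. Default 280.
#' @param d13c_air_permil Atmospheric delta13C, permil. Default -6.4.
#' @return An object of class `atmos` with attribute `mode = "constant"`.
#' @export
constant_atmosphere <- function(ca_ppm = 280, d13c_air_permil = -6.4) {
  if (ca_ppm <= 0) stop("ca_ppm must be positive")
  out <- data.frame(year = NA_integer_, ca_ppm = ca_ppm,
                    d13c_air_permil = d13c_air_permil)
  attr(out, "mode") <- "constant"
  class(out) <- c("atmos", "data.frame")
  out
}

#' Look up source air for given years
#'
#' Exact values at tabulated years, linear interpolation between them, and an
#' error outside the record's span (no extrapolation). A constant-mode record
#' answers every year.
#'
#' @param year Calendar year(s).
#' @param atmos An `atmos` object.
#' @return A data frame with columns `ca_ppm` and `d13c_air_permil`, one row
#'   per requested year.
#' @export
atmos_lookup <- function(year, atmos) {
  if (!inherits(atmos, "atmos")) stop("atmos must be an 'atmos' object")
  if (identical(attr(atmos, "mode"), "constant")) {
    return(data.frame(ca_ppm = rep(atmos$ca_ppm[1], length(year)),
                      d13c_air_permil = rep(atmos$d13c_air_permil[1],
                                            length(year))))
  }
  lo <- min(atmos$year)
  hi <- max(atmos$year)
  if (any(year < lo | year > hi))
    stop(sprintf("year(s) outside atmospheric record span %d-%d: %s",
                 lo, hi, paste(unique(year[year < lo | year > hi]),
                               collapse = ", ")))
  if (nrow(atmos) == 1) {
    return(data.frame(ca_ppm = rep(atmos$ca_ppm, length(year)),
                      d13c_air_permil = rep(atmos$d13c_air_permil,
                                            length(year))))
  }
  data.frame(
    ca_ppm = stats::approx(atmos$year, atmos$ca_ppm, xout = year)$y,
    d13c_air_permil = stats::approx(atmos$year, atmos$d13c_air_permil,
                                    xout = year)$y
  )
}
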