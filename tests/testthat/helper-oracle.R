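# Independent oracles, written step by step from the defining formulas and
# sharing no code with the package implementation.

# Step-by-step evaluation of the discrimination -> ci -> Wi chain.
oracle_gas_exchange <- function(d13c_plant, d13c_air, ca,
                                a = 4.4, b = 27, ratio = 1.6) {
  delta <- (d13c_air - d13c_plant) / (1 + d13c_plant / 1000)
  ci <- ca * (delta - a) / (b - a)
  wi <- (ca - ci) / ratio
  list(delta = delta, ci = ci, ci_over_ca = ci / ca,
       ca_minus_ci = ca - ci, wi = wi)
}

# Closed-form ordinary least squares from raw sums.
oracle_ols <- function(x, y) {
  n <- length(x)
  dx <- x - sum(x) / n
  dy <- y - sum(y) / n
  sxx <- sum(dx^2)
  sxy <- sum(dx * dy)
  syy <- sum(dy^2)
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  sse <- sum(resid^2)
  se <- sqrt(sse / (n - 2) / sxx)
  tval <- slope / se
  list(slope = slope, intercept = intercept, se = se,
       r_squared = 1 - sse / syy,
       p = 2 * stats::pt(abs(tval), n - 2, lower.tail = FALSE))
}

# Tiny well-formed tree table written to a temp CSV.
write_tree_fixture <- function(rows, path = tempfile(fileext = ".csv")) {
  header <- "tree_id,species,site_id,forest_type,sampling_year,age_years,dbh_cm,height_m,cii_class,d13c_outer_permil"
  writeLines(c(header, rows), path)
  path
}

good_tree_rows <- c(
  "T001,Fagus sylvatica,BW,temperate,2015,12,6.1,5.2,2b,-27.3",
  "T002,Fagus sylvatica,BW,temperate,2015,48,22.4,17.8,3b,-25.1",
  "T003,Fagus sylvatica,BW,temperate,2015,90,41.0,27.5,5,-23.9"
)
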