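# Air and water-vapour property functions shared by the thermal-index
# solvers. All take temperature in kelvin and pressure in Pa unless noted.

#' Saturation vapour pressure over liquid water
#'
#' Magnus-form formula (Alduchov-Eskridge coefficients):
#' \eqn{e_s = 610.94 \exp(17.625\,T / (243.04 + T))} with \eqn{T} in deg C and
#' the result in Pa. Used consistently for relative humidity, the wick
#' evaporation term, and sky emissivity so that all moisture conversions in
#' the package invert each other exactly.
#'
#' @param t_c temperature, deg C.
#' @return saturation vapour pressure, Pa.
#' @export
#' @examples
#' saturation_vapor_pressure(20) # about 2334 Pa
saturation_vapor_pressure <- function(t_c) {
  610.94 * exp(17.625 * t_c / (243.04 + t_c))
}

# dynamic viscosity of air, kg m-1 s-1 (Sutherland)
.air_viscosity <- function(t_k) 1.458e-6 * t_k^1.5 / (t_k + 110.4)

# thermal conductivity of air, W m-1 K-1 (Liljegren closure: k = (cp + 1.25 R) mu)
.air_conductivity <- function(t_k) {
  (.const$cp + 1.25 * .const$r_air) * .air_viscosity(t_k)
}

# binary diffusivity of water vapour in air, m2 s-1 (Chapman-Enskog style fit)
.h2o_diffusivity <- function(t_k, p_pa) {
  pcrit13 <- (.const$pcrit_air * .const$pcrit_h2o)^(1 / 3)
  tcrit512 <- (.const$tcrit_air * .const$tcrit_h2o)^(5 / 12)
  tcrit12 <- sqrt(.const$tcrit_air * .const$tcrit_h2o)
  mmix <- sqrt(1 / .const$m_air + 1 / .const$m_h2o)
  p_atm <- p_pa / 101325
  3.64e-4 * (t_k / tcrit12)^2.334 * pcrit13 * tcrit512 * mmix / p_atm * 1e-4
}

# latent heat of vaporisation, J kg-1 (linear in T around 2.43e6)
.latent_heat <- function(t_k) (313.15 - t_k) / 30 * (-71100) + 2.4073e6

# atmospheric (sky) emissivity from near-surface vapour pressure e (Pa)
.sky_emissivity <- function(e_pa) {
  e_hpa <- pmax(e_pa, 0) / 100
  pmin(0.575 * e_hpa^0.143, 1)
}

# vapour pressure (Pa) implied by specific humidity q (kg/kg) at pressure p
# (Pa); eps is the conventional 0.622 molar-mass ratio used throughout the
# package's moisture conversions
.vapor_pressure_from_q <- function(q, p_pa) {
  eps <- 0.622
  q * p_pa / (eps + (1 - eps) * q)
}

#' Relative humidity from specific humidity, temperature, and pressure
#'
#' Converts specific humidity to vapour pressure via the mixing-ratio
#' identity \eqn{e = q p / (\epsilon + (1-\epsilon) q)} with
#' \eqn{\epsilon = 0.622}, divides by the Magnus saturation pressure at the
#' air temperature, and clips to \eqn{[0, 100]} (supersaturated input maps
#' to 100).
#'
#' @param q specific humidity, kg/kg.
#' @param t_air_c dry-bulb air temperature, deg C (must lie in -60..60).
#' @param pressure_pa surface pressure, Pa.
#' @return relative humidity in percent, in \eqn{[0, 100]}. Vectorised.
#' @export
#' @examples
#' relative_humidity(0.00735, 20, 101325) # about 51 %
relative_humidity <- function(q, t_air_c, pressure_pa) {
  n <- max(length(q), length(t_air_c), length(pressure_pa))
  q <- rep_len(q, n); t_air_c <- rep_len(t_air_c, n)
  pressure_pa <- rep_len(pressure_pa, n)
  .check_field(q, "q", lower = 0)
  .check_field(t_air_c, "t_air", lower = -60, upper = 60)
  .check_field(pressure_pa, "pressure", lower = 0, strict = TRUE)
  e <- .vapor_pressure_from_q(q, pressure_pa)
  es <- saturation_vapor_pressure(t_air_c)
  pmin(pmax(100 * e / es, 0), 100)
}

# shared input validation: finite and within range, error names the field
.check_field <- function(x, name, lower = -Inf, upper = Inf, strict = FALSE) {
  if (any(!is.finite(x))) {
    stop("invalid input: non-finite value in field '", name, "'", call. = FALSE)
  }
  bad <- if (strict) x <= lower | x >= upper else x < lower | x > upper
  if (any(bad)) {
    stop("invalid input: field '", name, "' outside [", lower, ", ", upper,
         "] at position ", which(bad)[1], call. = FALSE)
  }
  invisible(TRUE)
}
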