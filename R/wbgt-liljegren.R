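# Outdoor WBGT components after Liljegren et al.: a black globe and a
# freely evaporating wick, each solved from an energy balance of absorbed
# solar + thermal radiation against convection, emission, and (for the
# wick) evaporation. Solvers are vectorised damped fixed-point iterations.

# convective coefficient, sphere in cross-flow (Ranz-Marshall), W m-2 K-1
.h_sphere <- function(t_k, p_pa, wind) {
  dens <- p_pa / (.const$r_air * t_k)
  re <- wind * dens * .const$d_globe / .air_viscosity(t_k)
  nu <- 2 + 0.6 * sqrt(re) * .const$pr^(1 / 3)
  nu * .air_conductivity(t_k) / .const$d_globe
}

# convective coefficient, cylinder in cross-flow (Bedingfield-Drew), W m-2 K-1
.h_cylinder <- function(t_k, p_pa, wind) {
  a <- 0.56; b <- 0.281; c <- 0.4
  dens <- p_pa / (.const$r_air * t_k)
  re <- wind * dens * .const$d_wick / .air_viscosity(t_k)
  nu <- a * re^(1 - c) * .const$pr^(1 - b)
  nu * .air_conductivity(t_k) / .const$d_wick
}

# recycle all arguments to common length and apply the wind-speed floor
.prep_met_args <- function(t_air_c, rh, pressure_pa, wind_ms, solar_wm2,
                           cza, fdir, wind_floor) {
  n <- max(length(t_air_c), length(rh), length(pressure_pa),
           length(wind_ms), length(solar_wm2))
  out <- list(
    t_air_c = rep_len(t_air_c, n), rh = rep_len(rh, n),
    pressure_pa = rep_len(pressure_pa, n), wind = rep_len(wind_ms, n),
    solar = rep_len(solar_wm2, n),
    cza = if (is.null(cza)) rep_len(1, n) else rep_len(cza, n),
    fdir = if (is.null(fdir)) rep_len(0, n) else rep_len(fdir, n)
  )
  .check_field(out$t_air_c, "t_air", lower = -60, upper = 60)
  .check_field(out$rh, "rh", lower = 0, upper = 100)
  .check_field(out$pressure_pa, "pressure", lower = 0, strict = TRUE)
  .check_field(out$wind, "wind", lower = 0)
  .check_field(out$solar, "solar", lower = 0)
  out$wind <- pmax(out$wind, wind_floor)
  # avoid 0 * Inf in the direct-beam geometry when the sun is down
  out$cza <- ifelse(out$fdir > 0, pmax(out$cza, 0.00873), 1)
  out
}

#' Globe temperature (Liljegren energy balance)
#'
#' Solves the steady-state energy balance of a standard 0.05 m black globe:
#' absorbed direct/diffuse shortwave plus thermal radiation from sky and
#' ground equals convective loss plus longwave emission. A damped
#' fixed-point iteration updates the globe temperature until successive
#' iterates differ by less than `tol`.
#'
#' @param t_air_c air temperature, deg C.
#' @param rh relative humidity, percent.
#' @param pressure_pa surface pressure, Pa.
#' @param wind_ms wind speed, m/s (floored at `wind_floor`).
#' @param solar_wm2 downward shortwave irradiance, W/m2.
#' @param cza cosine of the solar zenith angle; `NULL` treats all solar as
#'   diffuse (no beam geometry).
#' @param fdir fraction of `solar_wm2` that is direct beam; `NULL` means 0.
#' @param tol convergence tolerance on the iterate, deg C.
#' @param maxit iteration cap.
#' @param wind_floor minimum wind speed, m/s, keeping the convective
#'   correlations defined.
#' @return globe temperature, deg C, with attributes `residual` (energy
#'   balance imbalance, W/m2) and `converged` (logical vector).
#'   Non-convergence raises an error carrying the worst residual.
#' @export
globe_temperature <- function(t_air_c, rh, pressure_pa, wind_ms, solar_wm2,
                              cza = NULL, fdir = NULL,
                              tol = 1e-3, maxit = 100, wind_floor = 0.1) {
  a <- .prep_met_args(t_air_c, rh, pressure_pa, wind_ms, solar_wm2,
                      cza, fdir, wind_floor)
  ta <- c_to_k(a$t_air_c)
  e_air <- a$rh / 100 * saturation_vapor_pressure(a$t_air_c)
  ea <- .sky_emissivity(e_air)
  sb <- .const$stefanb; eg <- .const$emis_globe
  # absorbed shortwave flux per unit globe area (sphere geometry)
  solar_abs <- a$solar / 2 * (1 - .const$alb_globe) *
    (a$fdir * (1 / (2 * a$cza) - 1) + 1 + .const$alb_sfc)
  lw_in <- 0.5 * (ea * ta^4 + .const$emis_sfc * ta^4)

  # Newton iteration on the balance residual, which is monotone decreasing
  # in globe temperature (emission and convection both grow with it);
  # steps are clamped to +-10 K as a safeguard.
  tg <- ta
  converged <- rep(FALSE, length(ta))
  for (it in seq_len(maxit)) {
    tref <- 0.5 * (tg + ta)
    h <- .h_sphere(tref, a$pressure_pa, a$wind)
    f <- eg * sb * (lw_in - tg^4) - h * (tg - ta) + solar_abs
    step <- pmin(pmax(f / (4 * eg * sb * tg^3 + h), -10), 10)
    converged <- abs(step) < tol
    tg <- tg + step
    if (all(converged)) break
  }
  h <- .h_sphere(0.5 * (tg + ta), a$pressure_pa, a$wind)
  residual <- eg * sb * (lw_in - tg^4) - h * (tg - ta) + solar_abs
  if (!all(converged)) {
    stop("globe temperature solver failed to converge within ", maxit,
         " iterations; worst |residual| = ",
         signif(max(abs(residual[!converged])), 4), " W/m2", call. = FALSE)
  }
  structure(k_to_c(tg), residual = residual, converged = converged)
}

#' Natural wet-bulb temperature (Liljegren energy balance)
#'
#' Solves the wick energy balance for an unaspirated, sun-exposed wet wick:
#' convective and radiative gains balance evaporative cooling. In the
#' no-sun, well-ventilated limit the solution approaches the psychrometric
#' wet bulb; with radiation it sits above it.
#'
#' @inheritParams globe_temperature
#' @return natural wet-bulb temperature, deg C, with attributes `residual`
#'   (K, imbalance of the fixed-point map) and `converged`.
#' @export
natural_wet_bulb <- function(t_air_c, rh, pressure_pa, wind_ms, solar_wm2,
                             cza = NULL, fdir = NULL,
                             tol = 1e-3, maxit = 100, wind_floor = 0.1) {
  a <- .prep_met_args(t_air_c, rh, pressure_pa, wind_ms, solar_wm2,
                      cza, fdir, wind_floor)
  ta <- c_to_k(a$t_air_c)
  e_air <- a$rh / 100 * saturation_vapor_pressure(a$t_air_c)
  ea <- .sky_emissivity(e_air)
  sb <- .const$stefanb
  ratio_dw <- 0.25 * .const$d_wick / .const$l_wick
  # tan(zenith) for the direct-beam interception term; capped near sunset
  tanz <- ifelse(a$fdir > 0, tan(acos(pmin(pmax(a$cza, 0.05), 1))), 0)
  sw_abs <- (1 - .const$alb_wick) * a$solar *
    ((1 - a$fdir) * (1 + ratio_dw) + a$fdir * (tanz / pi + ratio_dw) +
       .const$alb_sfc)
  lw_in <- 0.5 * (ea * ta^4 + .const$emis_sfc * ta^4)

  # Stull's empirical wet bulb as the initial iterate (clamped to <= t_air)
  rh0 <- pmin(pmax(a$rh, 5), 99)
  tw0 <- a$t_air_c * atan(0.151977 * sqrt(rh0 + 8.313659)) +
    atan(a$t_air_c + rh0) - atan(rh0 - 1.676331) +
    0.00391838 * rh0^1.5 * atan(0.023101 * rh0) - 4.686035
  twb <- c_to_k(pmin(tw0, a$t_air_c))

  # Newton iteration on g(T) = map(T) - T, whose derivative is dominated by
  # the slope of the saturation curve at the wick; steps clamped to +-5 K.
  converged <- rep(FALSE, length(ta))
  g <- rep(0, length(ta))
  for (it in seq_len(maxit)) {
    tref <- 0.5 * (twb + ta)
    h <- .h_cylinder(tref, a$pressure_pa, a$wind)
    fatm <- sb * .const$emis_wick * (lw_in - twb^4) + sw_abs
    tw_c <- k_to_c(twb)
    ewick <- saturation_vapor_pressure(tw_c)
    des <- ewick * 17.625 * 243.04 / (243.04 + tw_c)^2
    dens <- a$pressure_pa / (.const$r_air * tref)
    sc <- .air_viscosity(tref) / (dens * .h2o_diffusivity(tref, a$pressure_pa))
    psych <- .latent_heat(tref) / .const$ratio * (.const$pr / sc)^0.56
    g <- ta -
      psych * (ewick - e_air) / (a$pressure_pa - ewick) +
      fatm / h - twb
    gp <- -(1 +
              psych * des * (a$pressure_pa - e_air) /
                (a$pressure_pa - ewick)^2 +
              4 * sb * .const$emis_wick * twb^3 / h)
    step <- pmin(pmax(-g / gp, -5), 5)
    converged <- abs(step) < tol
    twb <- twb + step
    if (all(converged)) break
  }
  residual <- g # K; zero at the fixed point
  if (!all(converged)) {
    stop("natural wet-bulb solver failed to converge within ", maxit,
         " iterations; worst |residual| = ",
         signif(max(abs(residual[!converged])), 4), " K", call. = FALSE)
  }
  structure(k_to_c(twb), residual = residual, converged = converged)
}

#' Outdoor wet-bulb globe temperature
#'
#' Fixed weighted combination of the three components:
#' \deqn{WBGT = 0.7\,T_{nwb} + 0.2\,T_g + 0.1\,T_{air}.}
#'
#' @param t_nwb natural wet-bulb temperature, deg C.
#' @param t_globe globe temperature, deg C.
#' @param t_air dry-bulb temperature, deg C.
#' @return WBGT in the same unit as the inputs (the weights sum to one, so
#'   the formula is valid in deg C or deg F alike).
#' @export
wbgt_outdoor <- function(t_nwb, t_globe, t_air) {
  if (any(!is.finite(t_nwb)) || any(!is.finite(t_globe)) ||
      any(!is.finite(t_air))) {
    stop("invalid input: non-finite WBGT component", call. = FALSE)
  }
  0.7 * t_nwb + 0.2 * t_globe + 0.1 * t_air
}

#' Cosine of the solar zenith angle
#'
#' Simple solar-position model: declination
#' \eqn{\delta = 23.45^\circ \sin(2\pi (284 + doy)/365)}, local solar time
#' from clock time plus the longitude correction
#' \eqn{4 (\lambda - 15\,U)} minutes for UTC offset \eqn{U}, and the hour
#' angle \eqn{H = 15^\circ (t_{solar} - 12)}. Adequate for partitioning
#' direct and diffuse irradiance; not an ephemeris.
#'
#' @param timestamp `POSIXct` in local standard time.
#' @param latitude,longitude site coordinates, degrees (east positive).
#' @param utc_offset hours ahead of UTC for the local standard clock
#'   (negative in the U.S.).
#' @return cosine of the zenith angle (negative when the sun is below the
#'   horizon).
#' @export
solar_zenith_cosine <- function(timestamp, latitude, longitude, utc_offset) {
  lt <- as.POSIXlt(timestamp, tz = "UTC")
  doy <- lt$yday + 1
  hour <- lt$hour + lt$min / 60 + lt$sec / 3600
  decl <- 23.45 * pi / 180 * sin(2 * pi * (284 + doy) / 365)
  solar_hour <- hour + 4 * (longitude - 15 * utc_offset) / 60
  hangle <- 15 * (solar_hour - 12) * pi / 180
  phi <- latitude * pi / 180
  sin(phi) * sin(decl) + cos(phi) * cos(decl) * cos(hangle)
}

#' Direct-beam fraction of global irradiance
#'
#' Liljegren clearness-index partitioning: with
#' \eqn{s^* = S / (S_0 \cos z)} capped at 0.85, the direct fraction is
#' \eqn{\exp(3 - 1.34 s^* - 1.65 / s^*)}, clipped to \eqn{[0, 0.9]};
#' zero when the sun is down or irradiance is zero.
#'
#' @param solar_wm2 downward shortwave irradiance, W/m2.
#' @param cza cosine of the solar zenith angle.
#' @return direct fraction in \eqn{[0, 0.9]}.
#' @export
direct_fraction <- function(solar_wm2, cza) {
  star <- ifelse(cza > 0.00873 & solar_wm2 > 0,
                 pmin(solar_wm2 / (.const$solar_const * pmax(cza, 0.00873)),
                      0.85),
                 NA_real_)
  fdir <- ifelse(is.na(star), 0, exp(3 - 1.34 * star - 1.65 / star))
  pmin(pmax(fdir, 0), 0.9)
}
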