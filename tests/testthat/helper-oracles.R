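# Independent oracles used to pin the physics and interval arithmetic.
# Each is written directly from the published formula it checks, separate
# from the package's implementation path.

# Magnus saturation pressure (Pa) and the mixing-ratio identities, written
# out independently for the humidity oracle.
oracle_esat <- function(t_c) 610.94 * exp(17.625 * t_c / (243.04 + t_c))

oracle_rh <- function(q, t_c, p_pa) {
  w <- q / (1 - q)                      # mixing ratio from specific humidity
  e <- w * p_pa / (0.622 + w)           # vapour pressure from mixing ratio
  100 * e / oracle_esat(t_c)
}

oracle_sat_q <- function(t_c, p_pa) {
  es <- oracle_esat(t_c)
  ws <- 0.622 * es / (p_pa - es)
  ws / (1 + ws)
}

# NWS heat index: Rothfusz regression plus the two published adjustments
# and the Steadman-average fallback, scalar form.
oracle_nws_hi <- function(t, rh) {
  simple <- 0.5 * (t + 61 + (t - 68) * 1.2 + rh * 0.094)
  if (simple < 80) return(simple)
  hi <- -42.379 + 2.04901523 * t + 10.14333127 * rh - 0.22475541 * t * rh -
    0.00683783 * t * t - 0.05481717 * rh * rh + 0.00122874 * t * t * rh +
    0.00085282 * t * rh * rh - 0.00000199 * t * t * rh * rh
  if (rh < 13 && t >= 80 && t <= 112) {
    hi <- hi - (13 - rh) / 4 * sqrt((17 - abs(t - 95)) / 17)
  } else if (rh > 85 && t >= 80 && t <= 87) {
    hi <- hi + (rh - 85) / 10 * (87 - t) / 5
  }
  hi
}

# Aspirated psychrometric wet bulb: root of es(Tw) - e = gamma P (T - Tw)
# with the WMO psychrometer coefficient gamma = 6.66e-4 / K.
oracle_psych_wetbulb <- function(t_c, rh, p_pa) {
  e <- rh / 100 * oracle_esat(t_c)
  stats::uniroot(function(tw) {
    oracle_esat(tw) - e - 6.66e-4 * p_pa * (t_c - tw)
  }, lower = -60, upper = t_c + 1e-9, tol = 1e-8)$root
}

# Type-7 empirical quantile from order statistics, written out by hand:
# index h = (n-1)p + 1, convex combination of the flanking order statistics.
oracle_quantile7 <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  g <- h - lo
  if (g == 0 || xs[hi] == xs[lo]) xs[lo] else (1 - g) * xs[lo] + g * xs[hi]
}

oracle_basic_ci <- function(reps, observed, alpha = 0.05) {
  c(2 * observed - oracle_quantile7(reps, 1 - alpha / 2),
    2 * observed - oracle_quantile7(reps, alpha / 2))
}

# Step-by-step BCa arithmetic: bias correction from the share of replicates
# below the observed value, acceleration from jackknife skewness, adjusted
# levels through the normal cdf, then type-7 quantiles.
oracle_bca_ci <- function(reps, observed, jack, alpha = 0.05) {
  z0 <- qnorm(sum(reps < observed) / length(reps))
  jm <- mean(jack)
  a <- sum((jm - jack)^3) / (6 * sum((jm - jack)^2)^1.5)
  adj <- function(z) pnorm(z0 + (z0 + z) / (1 - a * (z0 + z)))
  c(oracle_quantile7(reps, adj(qnorm(alpha / 2))),
    oracle_quantile7(reps, adj(qnorm(1 - alpha / 2))))
}

# A small, well-conditioned synthetic panel shared by model tests.
make_test_panel <- function(n_sites = 6, years = 2001:2012, seed = 11,
                            rr = 1.15, dispersion = 0.3) {
  sites <- default_sites(n_sites)
  truth <- truth_record(sites, rr_per_unit = rr, dispersion = dispersion)
  expo <- gen_annual_exposure(sites, years, seed = seed)
  panel <- gen_outcome_panel(expo, truth, sites, seed = seed + 1)
  list(sites = sites, truth = truth, expo = expo, panel = panel)
}

# Derived-hourly style table built directly (no solvers), giving full
# control of the values that the aggregation layer sees.
make_derived <- function(location_id, year, t_f_fun, seed = 1) {
  t0 <- as.POSIXct(paste0(year, "-01-01 00:00:00"), tz = "UTC")
  t1 <- as.POSIXct(paste0(year, "-12-31 23:00:00"), tz = "UTC")
  stamps <- seq(t0, t1, by = "hour")
  lt <- as.POSIXlt(stamps, tz = "UTC")
  t_f <- t_f_fun(lt$yday + 1, lt$hour)
  data.frame(location_id = location_id, timestamp = stamps,
             t_air_c = (t_f - 32) * 5 / 9,
             hi_f = t_f + 2, wbgt_f = t_f - 5)
}
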