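#' Derive hourly thermal indices from raw meteorology
#'
#' Applies [relative_humidity()], [heat_index()], [globe_temperature()],
#' [natural_wet_bulb()] and [wbgt_outdoor()] row-wise to an hourly
#' meteorology table, appending columns `rh_pct`, `hi_f`, `t_globe_c`,
#' `t_nwb_c`, and `wbgt_f` (heat index and WBGT reported in deg F, the
#' analysis base unit; solver components kept in deg C).
#'
#' When `sites` supplies coordinates, the solar zenith angle is computed
#' from each timestamp (assumed local standard time) and global irradiance
#' is partitioned into direct and diffuse beams; otherwise all solar is
#' treated as diffuse and a warning is issued.
#'
#' @param met data.frame with columns `location_id`, `timestamp` (`POSIXct`
#'   or ISO-8601 text, local standard time), `t_air_c`, `q_kgkg`,
#'   `pressure_pa`, `wind_ms`, `solar_wm2`.
#' @param sites optional data.frame with columns `location_id`, `latitude`,
#'   `longitude`, `utc_offset` used for solar geometry.
#' @param policy `"fail"` stops at the first invalid row, naming it;
#'   `"flag"` leaves derived fields `NA` for invalid rows.
#' @param tol,maxit,wind_floor solver controls passed to the energy-balance
#'   solvers.
#' @return the input data.frame with the five derived columns appended,
#'   rows aligned 1:1 with the input.
#' @export
derive_hourly <- function(met, sites = NULL, policy = c("fail", "flag"),
                          tol = 1e-3, maxit = 100, wind_floor = 0.1) {
  policy <- match.arg(policy)
  req <- c("location_id", "timestamp", "t_air_c", "q_kgkg", "pressure_pa",
           "wind_ms", "solar_wm2")
  missing_cols <- setdiff(req, names(met))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- met
  for (cn in c("rh_pct", "hi_f", "t_globe_c", "t_nwb_c", "wbgt_f")) {
    out[[cn]] <- rep(NA_real_, nrow(out))
  }
  if (nrow(met) == 0L) return(out)

  ts <- met$timestamp
  if (!inherits(ts, "POSIXct")) {
    ts <- as.POSIXct(as.character(ts), tz = "UTC",
                     tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                    "%Y-%m-%d %H:%M"))
  }
  key <- paste(met$location_id, format(ts, "%Y-%m-%d %H:%M"))
  if (anyDuplicated(key)) {
    stop("data integrity: duplicate (location_id, timestamp) at row ",
         which(duplicated(key))[1], call. = FALSE)
  }

  num <- c("t_air_c", "q_kgkg", "pressure_pa", "wind_ms", "solar_wm2")
  vals <- lapply(met[num], as.numeric)
  ok <- Reduce(`&`, lapply(vals, is.finite)) &
    vals$q_kgkg >= 0 & vals$pressure_pa > 0 & vals$wind_ms >= 0 &
    vals$solar_wm2 >= 0 & vals$t_air_c >= -60 & vals$t_air_c <= 60
  if (!all(ok)) {
    if (policy == "fail") {
      bad <- which(!ok)[1]
      badf <- num[!vapply(vals, function(v) is.finite(v[bad]), logical(1))]
      stop("invalid input at row ", bad,
           if (length(badf)) paste0(" (field ", badf[1], ")") else
             " (out-of-range value)", call. = FALSE)
    }
  }
  idx <- which(ok)
  if (!length(idx)) return(out)

  cza <- NULL; fdir <- NULL
  if (!is.null(sites)) {
    sreq <- c("location_id", "latitude", "longitude", "utc_offset")
    if (!all(sreq %in% names(sites))) {
      stop("sites must have columns ", paste(sreq, collapse = ", "),
           call. = FALSE)
    }
    m <- match(met$location_id[idx], sites$location_id)
    if (anyNA(m)) {
      stop("sites table lacks coordinates for location ",
           met$location_id[idx][which(is.na(m))[1]], call. = FALSE)
    }
    cza <- solar_zenith_cosine(ts[idx], sites$latitude[m],
                               sites$longitude[m], sites$utc_offset[m])
    fdir <- direct_fraction(vals$solar_wm2[idx], cza)
  } else {
    warning("no site coordinates supplied; treating all solar as diffuse",
            call. = FALSE)
  }

  rh <- relative_humidity(vals$q_kgkg[idx], vals$t_air_c[idx],
                          vals$pressure_pa[idx])
  tg <- globe_temperature(vals$t_air_c[idx], rh, vals$pressure_pa[idx],
                          vals$wind_ms[idx], vals$solar_wm2[idx],
                          cza = cza, fdir = fdir, tol = tol, maxit = maxit,
                          wind_floor = wind_floor)
  tw <- natural_wet_bulb(vals$t_air_c[idx], rh, vals$pressure_pa[idx],
                         vals$wind_ms[idx], vals$solar_wm2[idx],
                         cza = cza, fdir = fdir, tol = tol, maxit = maxit,
                         wind_floor = wind_floor)
  out$rh_pct[idx] <- rh
  out$hi_f[idx] <- heat_index(c_to_f(vals$t_air_c[idx]), rh)
  out$t_globe_c[idx] <- as.numeric(tg)
  out$t_nwb_c[idx] <- as.numeric(tw)
  out$wbgt_f[idx] <- c_to_f(wbgt_outdoor(as.numeric(tw), as.numeric(tg),
                                         vals$t_air_c[idx]))
  out
}
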