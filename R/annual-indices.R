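# Aggregation of hourly derived indices into the catalogue of thirty
# annual exposure indices: absolute and anomaly-based statistics of
# temperature, heat index, and WBGT over the full year or the heat season
# (01 May - 30 September). All values are in deg F at this layer.

.index_types <- c("temperature", "heat_index", "wbgt")

# hourly values (deg F) of one index type from a derived-hourly table
.hourly_value <- function(derived, index_type) {
  switch(index_type,
         temperature = c_to_f(derived$t_air_c),
         heat_index  = derived$hi_f,
         wbgt        = derived$wbgt_f,
         stop("unknown index_type: ", index_type, call. = FALSE))
}

.in_heat_season <- function(date) {
  m <- as.integer(format(date, "%m"))
  m >= 5L & m <= 9L
}

.window_filter <- function(date, window) {
  if (window == "heat_season") .in_heat_season(date) else rep(TRUE, length(date))
}

#' Daily summaries of derived hourly indices
#'
#' Collapses a derived hourly table to one row per (location, local
#' calendar date, index type) with the daily mean and maximum of the 24
#' hourly values. Days with fewer than `completeness * 24` hours present
#' are flagged incomplete; they are excluded from degree-valued annual
#' statistics but their hours still enter threshold-exceedance counts.
#'
#' @param derived output of [derive_hourly()].
#' @param completeness minimum fraction of the 24 hours a day must have to
#'   count as complete (default 0.9, i.e. at least 22 hours).
#' @return data.frame with columns `location_id`, `date`, `index_type`,
#'   `daily_mean`, `daily_max`, `n_hours`, `complete`. Values in deg F.
#' @export
daily_summaries <- function(derived, completeness = 0.9) {
  ts <- derived$timestamp
  if (!inherits(ts, "POSIXct")) {
    ts <- as.POSIXct(as.character(ts), tz = "UTC",
                     tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                    "%Y-%m-%d %H:%M"))
  }
  if (anyDuplicated(paste(derived$location_id, format(ts, "%Y-%m-%d %H")))) {
    stop("data integrity: duplicate (location_id, timestamp)", call. = FALSE)
  }
  date <- as.Date(format(ts, "%Y-%m-%d"))
  pieces <- lapply(.index_types, function(it) {
    dt <- data.table::data.table(location_id = derived$location_id,
                                 date = date,
                                 value = .hourly_value(derived, it))
    s <- dt[!is.na(value),
            list(daily_mean = mean(value), daily_max = max(value),
                 n_hours = .N),
            by = c("location_id", "date")]
    s[, "index_type" := it]
    s
  })
  out <- data.table::rbindlist(pieces)
  out[, "complete" := out$n_hours >= completeness * 24]
  data.table::setcolorder(out, c("location_id", "date", "index_type",
                                 "daily_mean", "daily_max", "n_hours",
                                 "complete"))
  data.table::setorderv(out, c("location_id", "index_type", "date"))
  as.data.frame(out)
}

#' Day-of-year climatology
#'
#' Per (location, index type, calendar day) mean and sample standard
#' deviation of the daily mean across the baseline years (default
#' 1990-2019). February 29 forms its own key, populated only by leap
#' years. Incomplete days are excluded.
#'
#' @param daily output of [daily_summaries()].
#' @param baseline_years length-2 integer vector, inclusive year range.
#' @return data.frame with columns `location_id`, `index_type`, `month`,
#'   `day`, `clim_mean`, `clim_sd`, `n_years`.
#' @export
build_climatology <- function(daily, baseline_years = c(1990, 2019)) {
  dt <- data.table::as.data.table(daily)
  yr <- as.integer(format(dt$date, "%Y"))
  dt <- dt[yr >= baseline_years[1] & yr <= baseline_years[2] & dt$complete]
  if (nrow(dt) == 0L) stop("no baseline data in range", call. = FALSE)
  dt[, c("month", "day") := list(as.integer(format(date, "%m")),
                                 as.integer(format(date, "%d")))]
  out <- dt[, list(clim_mean = mean(daily_mean),
                   clim_sd = stats::sd(daily_mean), n_years = .N),
            by = c("location_id", "index_type", "month", "day")]
  if (any(out$n_years < 2)) {
    bad <- out[out$n_years < 2][1]
    stop("climatology undefined (fewer than 2 baseline years) for ",
         bad$location_id, " ", bad$index_type, " ",
         sprintf("%02d-%02d", bad$month, bad$day), call. = FALSE)
  }
  data.table::setorderv(out, c("location_id", "index_type", "month", "day"))
  as.data.frame(out)
}

#' The catalogue of thirty annual indices
#'
#' Enumerates the full annual-index catalogue: for each of temperature,
#' heat index, and WBGT, the full-year and heat-season means of daily
#' means and daily maxima; full-year hour counts above fixed thresholds
#' (temperature 90/100 deg F, heat index 90/105 deg F, WBGT 85/90 deg F);
#' and, for both windows, the mean daily anomaly and the count of days
#' more than one climatological standard deviation above the day-of-year
#' norm.
#'
#' @return data.frame with columns `index_type`, `statistic`,
#'   `threshold_f` (`NA` except for `hours_above`), `window`; 30 rows.
#' @export
annual_index_catalogue <- function() {
  thresholds <- list(temperature = c(90, 100), heat_index = c(90, 105),
                     wbgt = c(85, 90))
  rows <- list()
  for (it in .index_types) {
    for (w in c("full_year", "heat_season")) {
      rows[[length(rows) + 1]] <- data.frame(
        index_type = it,
        statistic = c("mean_of_daily_mean", "mean_of_daily_max",
                      "mean_anomaly", "days_above_1sd"),
        threshold_f = NA_real_, window = w)
    }
    rows[[length(rows) + 1]] <- data.frame(
      index_type = it, statistic = "hours_above",
      threshold_f = thresholds[[it]], window = "full_year")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compute one annual index for one year
#'
#' Statistic semantics: `mean_of_daily_mean` and `mean_of_daily_max`
#' average complete window days; `hours_above` counts hourly values
#' strictly greater than the threshold over all available window hours;
#' `mean_anomaly` averages (daily mean - day-of-year climatological mean);
#' `days_above_1sd` counts complete window days whose daily mean is
#' strictly greater than the climatological mean plus one standard
#' deviation. Thresholds use strict `>`, so ties never count; when the
#' baseline is constant (`clim_sd == 0`) a day counts whenever it exceeds
#' the climatological mean.
#'
#' @param daily output of [daily_summaries()].
#' @param hourly output of [derive_hourly()] (needed for `hours_above`;
#'   may be `NULL` otherwise).
#' @param clim output of [build_climatology()] (needed for the relative
#'   statistics; may be `NULL` otherwise).
#' @param spec one-row data.frame (or list) with `index_type`,
#'   `statistic`, `threshold_f`, `window`.
#' @param year calendar year to evaluate.
#' @return data.frame with one row per location present: `location_id`,
#'   `year`, `index_type`, `statistic`, `threshold_f`, `window`, `value`.
#' @export
compute_annual_index <- function(daily, hourly, clim, spec, year) {
  it <- spec$index_type; st <- spec$statistic; w <- spec$window
  if (st == "hours_above") {
    if (is.null(hourly)) stop("hourly data required for hours_above",
                              call. = FALSE)
    ts <- hourly$timestamp
    if (!inherits(ts, "POSIXct")) {
      ts <- as.POSIXct(as.character(ts), tz = "UTC",
                       tryFormats = c("%Y-%m-%dT%H:%M:%S",
                                      "%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M"))
    }
    dte <- as.Date(format(ts, "%Y-%m-%d"))
    keep <- as.integer(format(dte, "%Y")) == year & .window_filter(dte, w)
    val <- .hourly_value(hourly, it)[keep]
    dt <- data.table::data.table(location_id = hourly$location_id[keep],
                                 value = val)
    agg <- dt[!is.na(value),
              list(value = as.numeric(sum(value > spec$threshold_f))),
              by = "location_id"]
  } else {
    d <- daily[daily$index_type == it &
                 as.integer(format(daily$date, "%Y")) == year &
                 .window_filter(daily$date, w) & daily$complete, ,
               drop = FALSE]
    dt <- data.table::as.data.table(d)
    if (st %in% c("mean_anomaly", "days_above_1sd")) {
      if (is.null(clim)) stop("climatology required for relative statistics",
                              call. = FALSE)
      cl <- clim[clim$index_type == it, , drop = FALSE]
      dt[, c("month", "day") := list(as.integer(format(date, "%m")),
                                     as.integer(format(date, "%d")))]
      cdt <- data.table::as.data.table(cl)
      dt <- cdt[dt, on = c("location_id", "month", "day")]
      if (anyNA(dt$clim_mean)) {
        miss <- dt[is.na(dt$clim_mean)][1]
        stop("missing climatology for ", miss$location_id, " ", it, " ",
             sprintf("%02d-%02d", miss$month, miss$day), call. = FALSE)
      }
    }
    agg <- switch(st,
      mean_of_daily_mean = dt[, list(value = mean(daily_mean)),
                              by = "location_id"],
      mean_of_daily_max  = dt[, list(value = mean(daily_max)),
                              by = "location_id"],
      mean_anomaly       = dt[, list(value = mean(daily_mean - clim_mean)),
                              by = "location_id"],
      days_above_1sd     = dt[, list(value = as.numeric(
                                sum(daily_mean > clim_mean + clim_sd))),
                              by = "location_id"],
      stop("unknown statistic: ", st, call. = FALSE))
  }
  if (nrow(agg) == 0L) {
    return(data.frame(location_id = character(), year = integer(),
                      index_type = character(), statistic = character(),
                      threshold_f = numeric(), window = character(),
                      value = numeric()))
  }
  data.frame(location_id = agg$location_id, year = year, index_type = it,
             statistic = st,
             threshold_f = if (is.null(spec$threshold_f)) NA_real_ else
               spec$threshold_f,
             window = w, value = agg$value)
}

#' Compute the full annual index catalogue
#'
#' Evaluates all thirty catalogue indices for every location and requested
#' year: 30 rows per location-year.
#'
#' @param derived output of [derive_hourly()].
#' @param clim output of [build_climatology()].
#' @param years integer vector of years to evaluate.
#' @param completeness passed to [daily_summaries()].
#' @return data.frame of annual index values, one row per
#'   (location, year, index specification).
#' @export
compute_all_indices <- function(derived, clim, years, completeness = 0.9) {
  if (nrow(derived) == 0L || length(years) == 0L) {
    return(data.frame(location_id = character(), year = integer(),
                      index_type = character(), statistic = character(),
                      threshold_f = numeric(), window = character(),
                      value = numeric()))
  }
  daily <- daily_summaries(derived, completeness = completeness)
  cat_ <- annual_index_catalogue()
  out <- list()
  for (y in years) {
    for (i in seq_len(nrow(cat_))) {
      out[[length(out) + 1]] <-
        compute_annual_index(daily, derived, clim, cat_[i, , drop = FALSE], y)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
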