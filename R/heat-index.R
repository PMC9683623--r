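#' NWS heat index
#'
#' Operational U.S. National Weather Service heat index. The simple
#' Steadman-average formula
#' \deqn{HI = 0.5 [T + 61 + 1.2 (T - 68) + 0.094\,RH]}
#' is evaluated first; when its value reaches the 80 deg F switchover the
#' Rothfusz multiple-regression form replaces it, together with the NWS
#' low-humidity adjustment (RH < 13 %, 80-112 deg F) and high-humidity
#' adjustment (RH > 85 %, 80-87 deg F). The hand-off follows the published
#' NWS procedure, so the two branches meet continuously at the switchover.
#'
#' @param t_air_f dry-bulb temperature, deg F.
#' @param rh relative humidity, percent in \eqn{[0, 100]}.
#' @return heat index, deg F. Vectorised.
#' @export
#' @examples
#' heat_index(96, 65) # about 121 deg F
heat_index <- function(t_air_f, rh) {
  n <- max(length(t_air_f), length(rh))
  t <- rep_len(t_air_f, n); rh <- rep_len(rh, n)
  .check_field(t, "t_air_f")
  .check_field(rh, "rh", lower = 0, upper = 100)

  hi <- 0.5 * (t + 61 + (t - 68) * 1.2 + rh * 0.094)
  hot <- hi >= 80
  if (any(hot)) {
    th <- t[hot]; rhh <- rh[hot]
    hr <- -42.379 + 2.04901523 * th + 10.14333127 * rhh -
      0.22475541 * th * rhh - 6.83783e-3 * th^2 - 5.481717e-2 * rhh^2 +
      1.22874e-3 * th^2 * rhh + 8.5282e-4 * th * rhh^2 -
      1.99e-6 * th^2 * rhh^2
    lo <- rhh < 13 & th >= 80 & th <= 112
    hr[lo] <- hr[lo] - (13 - rhh[lo]) / 4 * sqrt((17 - abs(th[lo] - 95)) / 17)
    hi_adj <- rhh > 85 & th >= 80 & th <= 87
    hr[hi_adj] <- hr[hi_adj] + (rhh[hi_adj] - 85) / 10 * (87 - th[hi_adj]) / 5
    hi[hot] <- hr
  }
  hi
}
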