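# Installation-year outcome panel: rates, combined rates, burden, and
# linear time trends for exposures and outcomes.

# valid year spans per outcome type (initial partially-reported years
# already excluded)
.outcome_spans <- list(ambulatory = c(1998L, 2018L),
                       hospitalization = c(1991L, 2018L),
                       reportable = c(1995L, 2018L))

#' HSI rate per 1,000 persons per year
#'
#' @param hsi_count heat stress illness encounter count.
#' @param population active-duty population (must be positive).
#' @return rate per 1,000 persons per year. Vectorised.
#' @export
#' @examples
#' hsi_rate(3612, 204291) # 17.68
hsi_rate <- function(hsi_count, population) {
  .check_field(hsi_count, "hsi_count", lower = 0)
  .check_field(population, "population", lower = 0, strict = TRUE)
  hsi_count / population * 1000
}

#' Combined rate across locations
#'
#' Pooled rate \eqn{\sum counts / \sum populations \times 1000} for a set
#' of records sharing one year and outcome type.
#'
#' @param records data.frame with columns `hsi_count`, `population`, and
#'   (if present, validated for uniqueness) `year` and `outcome_type`.
#' @return combined rate per 1,000 persons per year.
#' @export
combined_rate <- function(records) {
  if (nrow(records) == 0L) stop("no records", call. = FALSE)
  for (k in c("year", "outcome_type")) {
    if (k %in% names(records) && length(unique(records[[k]])) > 1L) {
      stop("invalid input: mixed ", k, " in combined_rate", call. = FALSE)
    }
  }
  hsi_rate(sum(records$hsi_count), sum(records$population))
}

#' HSI burden
#'
#' Percentage of HSI encounters among all documented injury and illness
#' encounters.
#'
#' @param hsi_count HSI encounter count.
#' @param all_count all-cause encounter count (must be positive).
#' @return burden in percent. Vectorised.
#' @export
hsi_burden <- function(hsi_count, all_count) {
  .check_field(hsi_count, "hsi_count", lower = 0)
  if (any(all_count <= 0)) {
    stop("invalid input: all_count must be positive", call. = FALSE)
  }
  hsi_count / all_count * 100
}

#' Linear time trend
#'
#' Ordinary least-squares regression of a series on calendar year, with
#' the two-sided t-test p-value for a non-zero slope (t distribution on
#' n - 2 degrees of freedom) and a significance flag at alpha = 0.05.
#'
#' @param values numeric series (an exposure index or an outcome rate).
#' @param years corresponding calendar years.
#' @param alpha significance level for the flag.
#' @return list with `slope` (units/year), `intercept`, `p_value`, `n`,
#'   `significant`.
#' @export
linear_trend <- function(values, years, alpha = 0.05) {
  if (length(values) != length(years)) {
    stop("values and years must have equal length", call. = FALSE)
  }
  keep <- is.finite(values) & is.finite(years)
  values <- values[keep]; years <- years[keep]
  n <- length(values)
  if (n < 3L) stop("need at least 3 points for a trend", call. = FALSE)
  if (stats::sd(years) == 0) {
    stop("constant years: singular design", call. = FALSE)
  }
  fit <- stats::lm(values ~ years)
  slope <- unname(coef(fit)[2])
  sxx <- sum((years - mean(years))^2)
  se <- sqrt(sum(fit$residuals^2) / (n - 2) / sxx)
  p <- if (se == 0) {
    if (slope == 0) 1 else 0 # exact fit: degenerate t statistic
  } else {
    2 * stats::pt(-abs(slope / se), df = n - 2)
  }
  list(slope = slope, intercept = unname(coef(fit)[1]),
       p_value = p, n = n, significant = p < alpha)
}
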