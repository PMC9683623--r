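# Negative-binomial rate model: installation-year counts with a log link,
# installation fixed effects (reference fixed at zero), and a log-population
# offset. The fitter alternates a fixed-theta GLM (MASS::negative.binomial
# family via stats::glm.fit) with maximum-likelihood dispersion updates
# (MASS::theta.ml) -- the glm.nb algorithm without formula overhead, which
# matters inside the bootstrap.

#' Model specification for the rate models
#'
#' Bundles the settings of one model run: bootstrap block length, number of
#' replicates, interval method, significance level, reference installation,
#' master seed, and the exposure increment that scales the rate ratio (1
#' deg F for degree indices, 1 hour or 1 day for count indices).
#'
#' @param reference location id of the reference installation (its fixed
#'   effect is pinned at zero; analogous to choosing the lowest-count site).
#' @param block_len bootstrap block length in years (1, 2, or 3).
#' @param n_boot number of bootstrap replicates.
#' @param ci_method one of `"basic"`, `"bca"`, `"percentile"`.
#' @param alpha two-sided interval level (0.05 gives 95 % CIs).
#' @param seed master seed; replicate r uses stream `seed + r`.
#' @param increment exposure step the rate ratio refers to.
#' @param year_term include a centred linear calendar-year term (the
#'   year-adjusted sensitivity variant).
#' @return a `model_spec` list.
#' @export
model_spec <- function(reference, block_len = 2L, n_boot = 2000L,
                       ci_method = c("basic", "bca", "percentile"),
                       alpha = 0.05, seed = 1L, increment = 1,
                       year_term = FALSE) {
  ci_method <- match.arg(ci_method)
  stopifnot(n_boot >= 1, alpha > 0, alpha < 1, increment > 0,
            block_len >= 1)
  structure(list(reference = reference, block_len = as.integer(block_len),
                 n_boot = as.integer(n_boot), ci_method = ci_method,
                 alpha = alpha, seed = as.integer(seed),
                 increment = increment, year_term = isTRUE(year_term)),
            class = "model_spec")
}

#' Build the model design from panel and exposure tables
#'
#' Joins the outcome panel to annual exposure values 1:1 on
#' (location, year) and assembles the response, design matrix (intercept,
#' exposure, indicator columns for every non-reference location, and
#' optionally a centred year term), and log-population offset.
#'
#' @param panel data.frame with `location_id`, `year`, `hsi_count`,
#'   `population` (one outcome type).
#' @param exposure data.frame with `location_id`, `year`, `value` (one
#'   index specification).
#' @param reference reference location id (indicator fixed at zero).
#' @param year_term add a centred calendar-year column.
#' @return list with `y`, `X`, `offset`, `year`, `location_id`,
#'   `reference`, `exposure_col` (column index of the exposure).
#' @export
build_design <- function(panel, exposure, reference, year_term = FALSE) {
  if (length(unique(panel$outcome_type %||% "one")) > 1L) {
    stop("panel must contain a single outcome type", call. = FALSE)
  }
  key_p <- paste(panel$location_id, panel$year)
  key_e <- paste(exposure$location_id, exposure$year)
  if (anyDuplicated(key_p)) {
    stop("data integrity: duplicate (location, year) in panel: ",
         key_p[duplicated(key_p)][1], call. = FALSE)
  }
  if (anyDuplicated(key_e)) {
    stop("data integrity: duplicate (location, year) in exposure: ",
         key_e[duplicated(key_e)][1], call. = FALSE)
  }
  m <- match(key_p, key_e)
  if (anyNA(m)) {
    stop("unmatched join keys (location, year): ",
         paste(utils::head(key_p[is.na(m)], 5), collapse = "; "),
         call. = FALSE)
  }
  locs <- sort(unique(panel$location_id))
  if (!reference %in% locs) {
    stop("reference location '", reference, "' absent from panel",
         call. = FALSE)
  }
  others <- setdiff(locs, reference)
  x_expo <- exposure$value[m]
  X <- cbind(`(Intercept)` = 1, index = x_expo)
  for (l in others) {
    X <- cbind(X, as.numeric(panel$location_id == l))
    colnames(X)[ncol(X)] <- paste0("loc_", l)
  }
  if (isTRUE(year_term)) {
    X <- cbind(X, year_c = panel$year - mean(panel$year))
  }
  if (any(panel$population <= 0)) {
    stop("invalid input: non-positive population", call. = FALSE)
  }
  list(y = as.numeric(panel$hsi_count), X = X,
       offset = log(panel$population), year = panel$year,
       location_id = panel$location_id, reference = reference,
       exposure_col = 2L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit the negative-binomial rate model
#'
#' Maximises the NB2 log-likelihood (variance \eqn{\mu + \alpha \mu^2})
#' with log link and fixed offset, estimating the dispersion jointly by
#' alternating fixed-theta weighted least squares with ML theta updates.
#' Non-convergence is reported through the `converged` flag rather than an
#' error, so bootstrap replicates can tolerate failures. Effectively
#' Poisson data drives theta to its cap (dispersion ~ 0) and reproduces
#' the Poisson fit.
#'
#' @param design output of [build_design()].
#' @param start optional starting coefficients (warm start).
#' @param init_theta optional starting theta (= 1/dispersion).
#' @param max_alt maximum theta/GLM alternations.
#' @return object of class `negbin_fit`: list with `coefficients`, `beta0`,
#'   `beta1`, `gamma` (named, reference = 0), `dispersion`, `theta`, `se`,
#'   `converged`, `log_lik`, `fitted`, `df_residual`.
#' @export
fit_negbin <- function(design, start = NULL, init_theta = NULL,
                       max_alt = 15L) {
  y <- design$y; X <- design$X; off <- design$offset
  if (all(y == 0)) stop("all-zero response", call. = FALSE)
  if (length(y) <= ncol(X)) {
    stop("need more rows than model columns", call. = FALSE)
  }
  theta_cap <- 1e5
  fail <- function() {
    structure(list(coefficients = rep(NA_real_, ncol(X)), beta0 = NA_real_,
                   beta1 = NA_real_, gamma = NULL, dispersion = NA_real_,
                   theta = NA_real_, se = NULL, converged = FALSE,
                   log_lik = NA_real_, fitted = NULL,
                   df_residual = length(y) - ncol(X), design = design),
              class = "negbin_fit")
  }
  est_theta <- function(mu) {
    th <- tryCatch(
      suppressWarnings(as.numeric(MASS::theta.ml(y, mu, limit = 25))),
      error = function(e) theta_cap)
    min(max(th, 1e-4), theta_cap)
  }
  res <- tryCatch({
    cf <- start
    th <- init_theta
    if (is.null(th)) {
      f0 <- suppressWarnings(glm.fit(X, y, family = poisson(), offset = off,
                                     start = cf,
                                     control = glm.control(maxit = 50)))
      cf <- f0$coefficients
      th <- est_theta(f0$fitted.values)
    }
    f <- NULL; ok <- FALSE
    for (it in seq_len(max_alt)) {
      fam <- MASS::negative.binomial(theta = th)
      f <- suppressWarnings(glm.fit(X, y, family = fam, offset = off,
                                    start = cf,
                                    control = glm.control(maxit = 50)))
      cf <- f$coefficients
      th_new <- est_theta(f$fitted.values)
      if (f$converged &&
          abs(log(th_new) - log(th)) < 1e-6 * (abs(log(th)) + 1)) {
        th <- th_new; ok <- TRUE; break
      }
      th <- th_new
    }
    if (anyNA(cf)) ok <- FALSE
    list(f = f, th = th, ok = ok)
  }, error = function(e) NULL)
  if (is.null(res) || is.null(res$f)) return(fail())

  f <- res$f; th <- res$th
  cf <- f$coefficients
  w <- f$weights
  se <- tryCatch(sqrt(diag(solve(crossprod(X * sqrt(w))))),
                 error = function(e) rep(NA_real_, ncol(X)))
  gamma_names <- grep("^loc_", colnames(X), value = TRUE)
  gamma <- setNames(c(0, cf[gamma_names]),
                    c(design$reference, sub("^loc_", "", gamma_names)))
  structure(list(
    coefficients = cf, beta0 = unname(cf[1]),
    beta1 = unname(cf[design$exposure_col]),
    gamma = gamma, dispersion = 1 / th, theta = th,
    se = setNames(se, colnames(X)), converged = res$ok,
    log_lik = sum(dnbinom(y, size = th, mu = f$fitted.values, log = TRUE)),
    fitted = f$fitted.values, df_residual = length(y) - ncol(X),
    design = design), class = "negbin_fit")
}

#' @export
print.negbin_fit <- function(x, ...) {
  cat("Negative-binomial rate model",
      if (!x$converged) "(NOT converged)" else "", "\n")
  cat("  beta1 (exposure):", format(x$beta1, digits = 4),
      " dispersion:", format(x$dispersion, digits = 4), "\n")
  cat("  log-likelihood:", format(x$log_lik, digits = 6), "\n")
  invisible(x)
}
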