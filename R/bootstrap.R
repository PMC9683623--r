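# Block bootstrap over calendar years for the rate models: resampled
# year-blocks are applied identically across installations so the panel's
# cross-sectional structure is preserved while serial correlation from
# shared secular trends is broken.

#' Resample years in consecutive blocks
#'
#' Draws `ceiling(T/L)` blocks of `L` consecutive years with replacement
#' (uniform start index) and concatenates them. When `L` does not divide
#' `T` the resampled series overshoots by up to `L - 1` years and is kept
#' untrimmed, matching the "approximate length" convention. `L = 1`
#' degenerates to ordinary resampling with replacement; `L = T` returns
#' the original series.
#'
#' @param years ordered vector of the observed years.
#' @param block_len block length `L` in years.
#' @param seed optional seed applied before drawing (the per-replicate
#'   stream of the bootstrap protocol).
#' @return integer vector of resampled years, length `ceiling(T/L) * L`.
#' @export
resample_blocks <- function(years, block_len, seed = NULL) {
  years <- sort(years)
  t_len <- length(years)
  if (t_len < block_len) {
    stop("series length ", t_len, " shorter than block length ", block_len,
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n_blocks <- ceiling(t_len / block_len)
  starts <- sample.int(t_len - block_len + 1L, n_blocks, replace = TRUE)
  unlist(lapply(starts, function(s) years[s:(s + block_len - 1L)]),
         use.names = FALSE)
}

#' Basic (empirical) bootstrap confidence interval
#'
#' \eqn{(2\hat\theta - Q_{1-\alpha/2},\; 2\hat\theta - Q_{\alpha/2})} where
#' `Q` is the type-7 empirical quantile of the replicate distribution.
#' Applied on the coefficient (log) scale before exponentiation to the
#' rate-ratio scale.
#'
#' @param replicates numeric vector of bootstrap statistics (>= 2).
#' @param observed observed statistic.
#' @param alpha interval level (0.05 for 95 %).
#' @return numeric `c(low, high)`.
#' @export
basic_ci <- function(replicates, observed, alpha = 0.05) {
  if (length(replicates) < 2L) stop("need at least 2 replicates",
                                    call. = FALSE)
  q <- stats::quantile(replicates, c(1 - alpha / 2, alpha / 2), type = 7,
                       names = FALSE)
  c(low = 2 * observed - q[1], high = 2 * observed - q[2])
}

#' Percentile bootstrap confidence interval
#'
#' @inheritParams basic_ci
#' @return numeric `c(low, high)`.
#' @export
percentile_ci <- function(replicates, alpha = 0.05) {
  if (length(replicates) < 2L) stop("need at least 2 replicates",
                                    call. = FALSE)
  q <- stats::quantile(replicates, c(alpha / 2, 1 - alpha / 2), type = 7,
                       names = FALSE)
  c(low = q[1], high = q[2])
}

#' Bias-corrected and accelerated (BCa) bootstrap interval
#'
#' Standard BCa construction: the bias correction
#' \eqn{z_0 = \Phi^{-1}(\#\{\theta^*_b < \hat\theta\}/B)} from the
#' proportion of replicates below the observed statistic, the acceleration
#' \eqn{a = \sum (\bar\theta_{(\cdot)} - \theta_{(i)})^3 / (6 [\sum
#' (\bar\theta_{(\cdot)} - \theta_{(i)})^2]^{3/2})} from jackknife
#' statistics (here leave-one-year-block-out), and type-7 quantiles of the
#' replicate distribution at the adjusted levels. A degenerate replicate
#' set (all equal to the observed statistic) collapses to a zero-width
#' interval; replicates entirely on one side of the observed statistic
#' make \eqn{z_0} infinite and raise an error.
#'
#' @param replicates bootstrap statistics (>= 2).
#' @param observed observed statistic.
#' @param jackknife jackknife statistics from leave-one-block-out refits.
#' @param alpha interval level.
#' @return numeric `c(low, high)`.
#' @export
bca_ci <- function(replicates, observed, jackknife, alpha = 0.05) {
  if (length(replicates) < 2L) stop("need at least 2 replicates",
                                    call. = FALSE)
  if (all(replicates == observed)) {
    return(c(low = observed, high = observed))
  }
  # proportion of replicates below the observed statistic; exact ties are
  # split evenly so symmetric replicate sets give a zero bias correction
  prop <- mean(replicates < observed) + 0.5 * mean(replicates == observed)
  if (prop == 0 || prop == 1) {
    stop("BCa undefined: all replicates on one side of the observed ",
         "statistic (proportion below = ", prop, ")", call. = FALSE)
  }
  z0 <- qnorm(prop)
  jm <- mean(jackknife)
  d <- jm - jackknife
  denom <- sum(d^2)^1.5
  a <- if (denom == 0) 0 else sum(d^3) / (6 * denom)
  zlo <- qnorm(alpha / 2); zhi <- qnorm(1 - alpha / 2)
  a1 <- pnorm(z0 + (z0 + zlo) / (1 - a * (z0 + zlo)))
  a2 <- pnorm(z0 + (z0 + zhi) / (1 - a * (z0 + zhi)))
  q <- stats::quantile(replicates, c(a1, a2), type = 7, names = FALSE)
  c(low = q[1], high = q[2])
}

#' Rate ratio from a log-scale coefficient
#'
#' @param beta1 exposure coefficient (log rate per exposure unit).
#' @param increment exposure step (1 deg F, 1 hour, or 1 day).
#' @return rate ratio \eqn{\exp(\beta_1 \times increment)}.
#' @export
rate_ratio <- function(beta1, increment = 1) {
  if (any(!is.finite(beta1)) || any(increment <= 0)) {
    stop("invalid input: beta1 must be finite and increment positive",
         call. = FALSE)
  }
  exp(beta1 * increment)
}

# stack design rows for a resampled year sequence (duplicates retained)
.stack_design <- function(design, years_seq, rows_by_year) {
  rows <- unlist(rows_by_year[as.character(years_seq)], use.names = FALSE)
  list(y = design$y[rows], X = design$X[rows, , drop = FALSE],
       offset = design$offset[rows], year = design$year[rows],
       location_id = design$location_id[rows],
       reference = design$reference, exposure_col = design$exposure_col)
}

#' Block-bootstrap rate-ratio estimation
#'
#' Fits the negative-binomial rate model on the observed panel, then for
#' each of `n_boot` replicates resamples the year series in blocks of
#' `block_len` (replicate r draws under seed `seed + r`, so results are
#' reproducible and order-independent), rebuilds the panel by stacking the
#' selected years across all installations, and refits with dispersion
#' re-estimated. The exposure coefficient is collected from converged
#' replicates; failures are counted, not imputed.
#'
#' @param panel outcome panel (one outcome type): `location_id`, `year`,
#'   `hsi_count`, `population`.
#' @param exposure annual index values (one specification): `location_id`,
#'   `year`, `value`.
#' @param spec a [model_spec()].
#' @return object of class `hsi_bootstrap`: list with `observed`
#'   ([fit_negbin()] result), `replicates` (beta1 values), `n_failed`,
#'   `rr` (observed-fit rate ratio), `rr_boot_mean` (rate ratio at the
#'   mean of replicates), `ci_low`, `ci_high` (rate-ratio scale),
#'   `method`, `alpha`, `block_len`, `n_boot`, `seed`, `increment`,
#'   `warning` (set when more than 20 % of replicates failed).
#' @export
block_bootstrap <- function(panel, exposure, spec) {
  stopifnot(inherits(spec, "model_spec"))
  design <- build_design(panel, exposure, spec$reference,
                         year_term = spec$year_term)
  observed <- fit_negbin(design)
  if (!observed$converged) {
    stop("observed fit did not converge", call. = FALSE)
  }
  years <- sort(unique(design$year))
  if (length(years) < spec$block_len) {
    stop("fewer years than block length", call. = FALSE)
  }
  rows_by_year <- split(seq_along(design$year), design$year)

  reps <- numeric(spec$n_boot)
  okv <- logical(spec$n_boot)
  for (r in seq_len(spec$n_boot)) {
    yrs <- resample_blocks(years, spec$block_len, seed = spec$seed + r)
    d_r <- .stack_design(design, yrs, rows_by_year)
    f_r <- fit_negbin(d_r, start = observed$coefficients,
                      init_theta = observed$theta)
    if (f_r$converged && is.finite(f_r$beta1)) {
      reps[r] <- f_r$beta1; okv[r] <- TRUE
    }
  }
  replicates <- reps[okv]
  n_failed <- spec$n_boot - length(replicates)
  if (n_failed == spec$n_boot) {
    stop("all bootstrap replicates failed", call. = FALSE)
  }
  warn <- if (n_failed > 0.2 * spec$n_boot) {
    paste0(n_failed, " of ", spec$n_boot, " replicates failed")
  } else NULL

  ci_beta <- switch(spec$ci_method,
    basic = basic_ci(replicates, observed$beta1, spec$alpha),
    percentile = percentile_ci(replicates, spec$alpha),
    bca = {
      jack <- .jackknife_blocks(design, observed, years, spec$block_len,
                                rows_by_year)
      bca_ci(replicates, observed$beta1, jack, spec$alpha)
    })
  structure(list(
    observed = observed, replicates = replicates, n_failed = n_failed,
    rr = rate_ratio(observed$beta1, spec$increment),
    rr_boot_mean = rate_ratio(mean(replicates), spec$increment),
    ci_low = unname(exp(ci_beta[1] * spec$increment)),
    ci_high = unname(exp(ci_beta[2] * spec$increment)),
    method = spec$ci_method, alpha = spec$alpha,
    block_len = spec$block_len, n_boot = spec$n_boot, seed = spec$seed,
    increment = spec$increment, warning = warn), class = "hsi_bootstrap")
}

# leave-one-block-out jackknife over the non-overlapping partition of the
# year series into consecutive blocks (deletion units for BCa)
.jackknife_blocks <- function(design, observed, years, block_len,
                              rows_by_year) {
  groups <- split(years, ceiling(seq_along(years) / block_len))
  vapply(groups, function(g) {
    keep_years <- setdiff(years, g)
    d_j <- .stack_design(design, keep_years, rows_by_year)
    f_j <- fit_negbin(d_j, start = observed$coefficients,
                      init_theta = observed$theta)
    if (f_j$converged) f_j$beta1 else NA_real_
  }, numeric(1)) |> stats::na.omit() |> as.numeric()
}

#' @export
print.hsi_bootstrap <- function(x, ...) {
  cat("Block-bootstrap rate ratio (", x$method, " CI, L = ", x$block_len,
      ", B = ", x$n_boot, ")\n", sep = "")
  cat(sprintf("  RR %.4f (%.4f, %.4f) per %g unit(s); boot-mean RR %.4f\n",
              x$rr, x$ci_low, x$ci_high, x$increment, x$rr_boot_mean))
  if (x$n_failed > 0) cat("  failed replicates:", x$n_failed, "\n")
  if (!is.null(x$warning)) cat("  warning:", x$warning, "\n")
  invisible(x)
}

#' Sensitivity suite of model variants
#'
#' Runs the five specification variants under a shared master seed: (a)
#' plain negative-binomial fit (Wald CI), (b) the same plus a centred
#' linear year term, and block bootstraps with block lengths 1, 2, and 3
#' (basic CIs). Per-variant errors are recorded in the output, not raised.
#'
#' @inheritParams block_bootstrap
#' @return data.frame with one row per variant: `variant`, `rr`, `ci_low`,
#'   `ci_high`, `method`, `n_boot`, `n_failed`, `error`.
#' @export
sensitivity_suite <- function(panel, exposure, spec) {
  stopifnot(inherits(spec, "model_spec"))
  z <- qnorm(1 - spec$alpha / 2)
  wald_row <- function(variant, year_term) {
    d <- build_design(panel, exposure, spec$reference, year_term = year_term)
    f <- fit_negbin(d)
    if (!f$converged) stop("fit did not converge")
    se1 <- unname(f$se[d$exposure_col])
    data.frame(variant = variant,
               rr = rate_ratio(f$beta1, spec$increment),
               ci_low = exp((f$beta1 - z * se1) * spec$increment),
               ci_high = exp((f$beta1 + z * se1) * spec$increment),
               method = "wald", n_boot = NA_integer_,
               n_failed = NA_integer_, error = NA_character_)
  }
  boot_row <- function(variant, L) {
    sp <- spec; sp$block_len <- as.integer(L); sp$ci_method <- "basic"
    sp$year_term <- FALSE
    b <- block_bootstrap(panel, exposure, sp)
    data.frame(variant = variant, rr = b$rr, ci_low = b$ci_low,
               ci_high = b$ci_high, method = "basic_boot",
               n_boot = sp$n_boot, n_failed = b$n_failed,
               error = NA_character_)
  }
  tasks <- list(
    nb_plain = function() wald_row("nb_plain", FALSE),
    nb_year = function() wald_row("nb_year", TRUE),
    boot_block1 = function() boot_row("boot_block1", 1L),
    boot_block2 = function() boot_row("boot_block2", 2L),
    boot_block3 = function() boot_row("boot_block3", 3L))
  rows <- lapply(names(tasks), function(nm) {
    tryCatch(tasks[[nm]](), error = function(e) {
      data.frame(variant = nm, rr = NA_real_, ci_low = NA_real_,
                 ci_high = NA_real_, method = NA_character_,
                 n_boot = NA_integer_, n_failed = NA_integer_,
                 error = conditionMessage(e))
    })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Project case burden under an exposure shift
#'
#' Applies a rate ratio per exposure unit to a baseline count:
#' \eqn{projected = round(baseline \times RR^{\Delta})}. Negative
#' `delta_units` describe a cooling scenario.
#'
#' @param baseline_count observed baseline count (>= 0).
#' @param rr_per_unit rate ratio per unit exposure increase (> 0).
#' @param delta_units exposure change in the same units.
#' @return list with `projected` and `delta` (projected - baseline).
#' @export
#' @examples
#' project_counts(3612, 1.16, 1) # 4190 cases, +578
project_counts <- function(baseline_count, rr_per_unit, delta_units) {
  if (baseline_count < 0) stop("baseline_count must be >= 0", call. = FALSE)
  if (!is.finite(rr_per_unit) || rr_per_unit <= 0) {
    stop("rate ratio must be positive", call. = FALSE)
  }
  projected <- round(baseline_count * rr_per_unit^delta_units)
  list(projected = projected, delta = projected - baseline_count)
}
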