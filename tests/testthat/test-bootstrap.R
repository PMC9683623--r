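test_that("resample_blocks draws consecutive blocks of the stated length", {
  yrs <- 1991:2018
  s <- resample_blocks(yrs, 2, seed = 7)
  expect_equal(length(s), 28) # 14 blocks of 2
  # every block is two consecutive years
  starts <- s[seq(1, 27, by = 2)]
  expect_equal(s[seq(2, 28, by = 2)], starts + 1)
  expect_true(all(s %in% yrs))

  # odd series length overshoots by one and is kept untrimmed
  expect_equal(length(resample_blocks(1991:2017, 2, seed = 1)), 28)
  # L = 1 is ordinary resampling; L = T returns the series itself
  expect_equal(length(resample_blocks(yrs, 1, seed = 1)), 28)
  expect_equal(resample_blocks(yrs, 28, seed = 1), yrs)
  expect_error(resample_blocks(2001:2003, 5), "shorter")
  # reproducible under seed
  expect_identical(resample_blocks(yrs, 2, seed = 9),
                   resample_blocks(yrs, 2, seed = 9))
})

test_that("basic CI matches the order-statistics oracle exactly", {
  expect_equal(unname(basic_ci(c(-2, -1, 0, 1, 2), 0)),
               oracle_basic_ci(c(-2, -1, 0, 1, 2), 0))
  set.seed(13)
  for (n in c(3, 5, 7, 10)) {
    reps <- rnorm(n)
    obs <- rnorm(1)
    expect_equal(unname(basic_ci(reps, obs)), oracle_basic_ci(reps, obs))
    expect_equal(unname(basic_ci(reps, obs, alpha = 0.1)),
                 oracle_basic_ci(reps, obs, alpha = 0.1))
  }
  # degenerate replicate set collapses on the observed value
  expect_equal(unname(basic_ci(rep(1.5, 5), 1.5)), c(1.5, 1.5))
  expect_error(basic_ci(1, 0), "at least 2")
})

test_that("basic CI equals percentile CI for symmetric replicates", {
  reps <- c(-3, -1, 0, 1, 3) + 2 # symmetric about observed = 2
  b <- basic_ci(reps, 2)
  p <- percentile_ci(reps)
  expect_equal(unname(b), unname(p))
})

test_that("BCa matches hand arithmetic and its invariances", {
  reps <- c(0.8, 1.1, 1.3, 1.9, 2.4, 2.5, 3.2, 4.1)
  obs <- 2.0
  jack <- c(1.6, 1.9, 2.1, 2.6, 2.2, 1.8)
  expect_equal(unname(bca_ci(reps, obs, jack)),
               oracle_bca_ci(reps, obs, jack))
  set.seed(17)
  for (i in 1:5) {
    reps <- rnorm(10); obs <- stats::median(reps); jack <- rnorm(6)
    expect_equal(unname(bca_ci(reps, obs, jack)),
                 oracle_bca_ci(reps, obs, jack))
    # shifting everything by c shifts both bounds by c
    shifted <- bca_ci(reps + 3, obs + 3, jack + 3)
    expect_equal(unname(shifted), unname(bca_ci(reps, obs, jack)) + 3,
                 tolerance = 1e-12)
  }
  # symmetric replicates with zero acceleration reduce to percentile
  reps <- c(-2, -1, 0, 1, 2)
  expect_equal(unname(bca_ci(reps, 0, jackknife = c(-1, 0, 1))),
               unname(percentile_ci(reps)))
  # all replicates on one side of the observed statistic is an error
  expect_error(bca_ci(c(1, 2, 3), 0, jack), "one side")
  # degenerate set collapses
  expect_equal(unname(bca_ci(rep(2, 4), 2, jack)), c(2, 2))
})

test_that("rate ratios exponentiate the scaled coefficient", {
  expect_equal(rate_ratio(0), 1)
  expect_equal(rate_ratio(log(1.16), 1), 1.16)
  expect_equal(rate_ratio(log(1.16), 2), 1.16^2)
  # monotone in beta1 and in increment for positive beta1
  expect_true(all(diff(rate_ratio(seq(-1, 1, 0.1))) > 0))
  expect_true(all(diff(rate_ratio(0.2, increment = 1:5)) > 0))
  expect_error(rate_ratio(Inf), "finite")
})

test_that("block bootstrap accounts for every replicate", {
  w <- make_test_panel(n_sites = 5, years = 2001:2012)
  spec <- model_spec(reference = "site_01", n_boot = 60, seed = 5)
  b <- block_bootstrap(w$panel, w$expo, spec)
  expect_equal(length(b$replicates) + b$n_failed, 60)
  expect_lte(b$ci_low, b$ci_high)
  expect_equal(b$rr, exp(b$observed$beta1))
  # reproducible under the same master seed, order-independent streams
  b2 <- block_bootstrap(w$panel, w$expo, spec)
  expect_identical(b$replicates, b2$replicates)
})

test_that("whole-series blocks collapse all intervals to the point", {
  w <- make_test_panel(n_sites = 5, years = 2001:2010)
  for (m in c("basic", "percentile")) {
    spec <- model_spec(reference = "site_01", block_len = 10, n_boot = 20,
                       ci_method = m, seed = 3)
    b <- block_bootstrap(w$panel, w$expo, spec)
    expect_equal(max(abs(b$replicates - b$observed$beta1)), 0,
                 tolerance = 1e-6)
    expect_equal(b$ci_low, b$rr, tolerance = 1e-5)
    expect_equal(b$ci_high, b$rr, tolerance = 1e-5)
  }
})

test_that("unit blocks reproduce an independent simple bootstrap", {
  w <- make_test_panel(n_sites = 5, years = 2001:2010)
  n_boot <- 25
  spec <- model_spec(reference = "site_01", block_len = 1, n_boot = n_boot,
                     seed = 19)
  b <- block_bootstrap(w$panel, w$expo, spec)

  # independent implementation: ordinary year resampling + MASS::glm.nb
  dat <- w$panel
  dat$value <- w$expo$value[match(paste(dat$location_id, dat$year),
                                  paste(w$expo$location_id, w$expo$year))]
  years <- sort(unique(dat$year))
  reps <- vapply(seq_len(n_boot), function(r) {
    set.seed(19 + r)
    yrs <- years[sample.int(length(years), length(years), replace = TRUE)]
    stacked <- do.call(rbind, lapply(yrs, function(y) dat[dat$year == y, ]))
    fit <- suppressWarnings(
      MASS::glm.nb(hsi_count ~ value + factor(location_id) +
                     offset(log(population)), data = stacked))
    unname(coef(fit)["value"])
  }, numeric(1))
  expect_equal(sort(b$replicates), sort(reps), tolerance = 1e-4)
})

test_that("BCa block bootstrap runs with leave-one-block-out jackknife", {
  w <- make_test_panel(n_sites = 5, years = 2001:2012)
  spec <- model_spec(reference = "site_01", n_boot = 60, seed = 5,
                     ci_method = "bca")
  b <- block_bootstrap(w$panel, w$expo, spec)
  expect_equal(b$method, "bca")
  expect_true(is.finite(b$ci_low) && is.finite(b$ci_high))
  expect_lt(b$ci_low, b$ci_high)
  # interval sits in the bulk of the replicate distribution
  expect_gt(b$ci_high, exp(min(b$replicates)))
  expect_lt(b$ci_low, exp(max(b$replicates)))
})

test_that("the sensitivity suite reports its five variants", {
  w <- make_test_panel(n_sites = 5, years = 2001:2012)
  spec <- model_spec(reference = "site_01", n_boot = 25, seed = 8)
  out <- sensitivity_suite(w$panel, w$expo, spec)
  expect_equal(nrow(out), 5)
  expect_equal(out$variant, c("nb_plain", "nb_year", "boot_block1",
                              "boot_block2", "boot_block3"))
  expect_true(all(is.na(out$error)))
  expect_true(all(out$ci_low <= out$ci_high))
  expect_equal(out$method[1:2], c("wald", "wald"))
})

test_that("projection arithmetic applies the rate ratio to the baseline", {
  p <- project_counts(3612, 1.16, 1)
  expect_identical(p$projected, 4190)
  expect_identical(p$delta, 578)
  expect_equal(project_counts(1000, 1, 3)$delta, 0)
  expect_equal(project_counts(3612, 1.16, 2)$projected,
               round(3612 * 1.16^2))
  # cooling scenario reduces the burden
  expect_lt(project_counts(1000, 1.2, -1)$projected, 1000)
  expect_error(project_counts(100, -1, 1), "positive")
})
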