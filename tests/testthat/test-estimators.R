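test_that("closed-form common HR reproduces the worked matched-cohort example", {
  est <- common_hr_pmle(pair_counts(n1 = 198, n2 = 135))
  expect_equal(est$hr, 198 / 135)
  expect_equal(round(est$hr, 2), 1.47)
  expect_equal(est$se, sqrt(1 / 198 + 1 / 135))
  expect_equal(round(est$ci_low, 2), 1.18)
  expect_equal(round(est$ci_high, 2), 1.83)
})

test_that("symmetric counts give HR 1 and the stated variance", {
  est <- common_hr_pmle(pair_counts(n1 = 10, n2 = 10))
  expect_equal(est$hr, 1)
  expect_equal(est$se, sqrt(0.2))
  expect_true(est$ci_low < 1 && est$ci_high > 1)
})

test_that("boundary and empty counts raise informative errors", {
  expect_error(common_hr_pmle(pair_counts(n1 = 5)), "diverges")
  expect_error(common_hr_pmle(pair_counts(n2 = 5)), "diverges to 0")
  expect_error(common_hr_pmle(pair_counts()), "not estimable")
  expect_error(stratified_logrank(pair_counts()), "undefined")
  expect_error(pair_c_statistic(pair_counts()), "undefined")
})

test_that("closed form equals the iteratively maximized stratified partial likelihood", {
  for (seed in c(2, 31)) {
    ph <- rand_cohort(200, seed = seed)
    counts <- tabulate_pairs(ph)
    fit <- fit_cox(pairs_to_long(ph), covariates = "exposure",
                   strata = "pair_id")
    expect_equal(unname(fit$beta), log(counts$G / counts$H), tolerance = 1e-8)
    expect_equal(unname(fit$se_model)^2, 1 / counts$G + 1 / counts$H,
                 tolerance = 1e-8)
  }
})

test_that("stratified log-rank statistic and its chi-squared tail", {
  expect_equal(stratified_logrank(pair_counts(n1 = 50, n2 = 50))$statistic, 0)
  expect_equal(stratified_logrank(pair_counts(n1 = 50, n2 = 50))$p_value, 1)
  ts <- stratified_logrank(pair_counts(n1 = 198, n2 = 135))
  expect_equal(ts$statistic, 63^2 / 333)
  expect_equal(ts$p_value, pchisq(63^2 / 333, 1, lower.tail = FALSE))
})

test_that("stratified log-rank equals the partial-likelihood score test", {
  for (seed in 1:10) {
    ph <- rand_cohort(60, seed = 100 + seed, round_digits = 1)
    counts <- tabulate_pairs(ph)
    st <- score_test_null(pairs_to_long(ph), covariates = "exposure",
                          strata = "pair_id")
    expect_equal(st$statistic, stratified_logrank(counts)$statistic,
                 tolerance = 1e-12)
  }
})

test_that("C-statistic odds reproduce the common hazard ratio", {
  cs <- pair_c_statistic(pair_counts(n1 = 198, n2 = 135))
  expect_equal(cs$c, 198 / 333)
  expect_equal(cs$c / (1 - cs$c), 198 / 135)
  expect_identical(cs$direction, "exposed")

  expect_equal(pair_c_statistic(pair_counts(n1 = 7, n2 = 7))$c, 0.5)

  swapped <- pair_c_statistic(pair_counts(n1 = 135, n2 = 198))
  expect_equal(swapped$c, 198 / 333)
  expect_identical(swapped$direction, "unexposed")

  # odds identity against the PMLE on random cohorts
  ph <- rand_cohort(150, seed = 44)
  counts <- tabulate_pairs(ph)
  est <- common_hr_pmle(counts)
  cs2 <- pair_c_statistic(counts)
  expect_equal(cs2$c / (1 - cs2$c), exp(abs(est$log_hr)))
})

test_that("Mantel-Haenszel rate ratio evaluates its defining formula", {
  one <- pair_data("k", x1 = 1, y1 = 1, x0 = 2, y0 = 1)
  expect_equal(mh_rate_ratio(one)$hr, (2 / 3) / (1 / 3))
  none <- pair_data(1:3, x1 = c(1, 2, 3), y1 = 0, x0 = c(2, 1, 4), y0 = 0)
  expect_error(mh_rate_ratio(none), "no events")
  exposed_only <- pair_data(1:2, x1 = c(1, 2), y1 = 1, x0 = c(2, 3), y0 = 0)
  expect_error(mh_rate_ratio(exposed_only), "diverges")
})

test_that("conditional-Poisson MLE solves its estimating equation", {
  one <- pair_data("k", x1 = 1, y1 = 1, x0 = 1, y0 = 1)
  expect_equal(poisson_cmle(one)$hr, 1, tolerance = 1e-8)

  no_unexposed <- pair_data(1:4, x1 = 1:4, y1 = 1, x0 = 2:5, y0 = 0)
  expect_error(poisson_cmle(no_unexposed), "boundary")

  # grid-search oracle: the sign change of the estimating function
  for (seed in c(6, 60)) {
    ph <- rand_cohort(120, seed = seed)
    est <- poisson_cmle(ph)
    ee <- function(log_hr) {
      hr <- exp(log_hr)
      sum((ph$y1 * ph$x0 - hr * ph$y0 * ph$x1) / (ph$x0 + hr * ph$x1))
    }
    grid <- seq(est$log_hr - 0.01, est$log_hr + 0.01, by = 1e-8 * 100)
    vals <- vapply(grid, ee, numeric(1))
    flip <- which(diff(sign(vals)) != 0)[1]
    expect_lt(abs(grid[flip] - est$log_hr), 1e-4)
    # the estimating function is decreasing through the root
    expect_gt(ee(est$log_hr - 0.5), 0)
    expect_lt(ee(est$log_hr + 0.5), 0)
  }
})

test_that("MH rate ratio approximates the Poisson CMLE near the null", {
  # the two estimating functions coincide at HR = 1, so the estimators
  # agree as the realized estimate approaches the null, with a gap
  # proportional to its distance from 0; a Monte-Carlo average over
  # null cohorts measures that first-order agreement
  diffs <- ests <- numeric(20)
  for (i in seq_along(diffs)) {
    ph <- draw_cohort(scenario_config(2000, beta = 0), seed = 70 + i)
    diffs[i] <- abs(mh_rate_ratio(ph)$log_hr - poisson_cmle(ph)$log_hr)
    ests[i] <- abs(poisson_cmle(ph)$log_hr)
  }
  expect_lt(mean(diffs), 0.02)
  # the gap vanishes with the distance from the null, not just on average
  expect_true(all(diffs <= 0.5 * ests + 0.005))
})

test_that("every estimator is antisymmetric under exposure relabeling", {
  ph <- rand_cohort(150, seed = 21)
  sw <- swap_exposure(ph)
  expect_equal(common_hr_pmle(tabulate_pairs(sw))$log_hr,
               -common_hr_pmle(tabulate_pairs(ph))$log_hr)
  expect_equal(mh_rate_ratio(sw)$log_hr, -mh_rate_ratio(ph)$log_hr)
  expect_equal(poisson_cmle(sw)$log_hr, -poisson_cmle(ph)$log_hr,
               tolerance = 1e-6)
  fit <- fit_cox(pairs_to_long(ph), covariates = "exposure")
  fit_sw <- fit_cox(pairs_to_long(sw), covariates = "exposure")
  expect_equal(unname(fit_sw$beta), -unname(fit$beta), tolerance = 1e-7)
  # the test statistic is symmetric
  expect_equal(stratified_logrank(tabulate_pairs(sw))$statistic,
               stratified_logrank(tabulate_pairs(ph))$statistic)
})

test_that("McNemar alias counts discordant event indicators only", {
  ph <- pair_data(1:6, x1 = c(1, 1, 2, 2, 3, 3), y1 = c(1, 1, 1, 0, 0, 0),
                  x0 = c(2, 2, 1, 1, 4, 4), y0 = c(0, 0, 0, 1, 1, 0))
  ts <- mcnemar_test(ph)   # B = 3 exposed-only, C = 2 unexposed-only
  expect_equal(ts$statistic, (3 - 2)^2 / 5)
  all_conc <- pair_data(1:2, x1 = c(1, 2), y1 = c(1, 0),
                        x0 = c(2, 3), y0 = c(1, 0))
  expect_error(mcnemar_test(all_conc), "discordant")
})
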