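make_covariate_table <- function(n, seed) {
  set.seed(seed)
  age <- rnorm(n, 55, 10)
  size <- rbinom(n, 1, 0.4)
  lp <- -0.03 * (age - 55) + 0.8 * size
  data.frame(subject_id = sprintf("s%03d", seq_len(n)),
             age = age, size = size,
             exposure = rbinom(n, 1, plogis(lp)))
}

test_that("intercept-only propensity model returns the exposure prevalence", {
  d <- data.frame(exposure = rep(c(1, 0), c(30, 70)), one = 0)
  sc <- fit_propensity(d, character(0))
  expect_equal(unique(round(sc, 10)), 0.3)
  # a constant covariate is collinear with the intercept
  expect_error(fit_propensity(d, "one"), "collinear")
})

test_that("a single binary covariate reproduces the saturated cell proportions", {
  d <- data.frame(g = rep(c(0, 1), c(40, 60)),
                  exposure = c(rep(c(1, 0), c(10, 30)), rep(c(1, 0), c(45, 15))))
  sc <- fit_propensity(d, "g")
  expect_equal(unique(round(sc[d$g == 0], 10)), 10 / 40)
  expect_equal(unique(round(sc[d$g == 1], 10)), 45 / 60)
})

test_that("logistic coefficients match a direct likelihood optimizer", {
  d <- make_covariate_table(200, seed = 31)
  sc <- fit_propensity(d, c("age", "size"))
  co <- attr(sc, "coefficients")
  X <- cbind(1, d$age, d$size)
  negll <- function(b) {
    eta <- drop(X %*% b)
    -sum(d$exposure * eta - log1p(exp(eta)))
  }
  grad <- function(b) -drop(crossprod(X, d$exposure - plogis(drop(X %*% b))))
  opt <- optim(c(0, 0, 0), negll, grad, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-15))
  expect_equal(unname(co), opt$par, tolerance = 1e-6)
})

test_that("separation and collinearity are reported", {
  d <- data.frame(exposure = rep(c(0, 1), each = 20),
                  z = rep(c(-1, 1), each = 20))
  expect_error(fit_propensity(d, "z"), "separation|converge")
  d2 <- make_covariate_table(60, seed = 5)
  d2$age2 <- 2 * d2$age
  expect_error(fit_propensity(d2, c("age", "age2")), "collinear.*age")
})

test_that("caliper matching pairs nearest neighbors without replacement", {
  sc <- c(0.4, 0.6, 0.41, 0.59)
  ex <- c(1, 1, 0, 0)
  m <- caliper_match(sc, ex, ids = c("e1", "e2", "u1", "u2"),
                     caliper_sd_fraction = 3)
  expect_identical(m$n_matched, 2L)
  got <- m$pairs[order(m$pairs$exposed_id), ]
  expect_identical(got$unexposed_id, c("u1", "u2"))
  expect_true(all(got$ps_distance <= m$caliper))

  # disjoint score ranges with a tight caliper: nothing matches
  m0 <- caliper_match(c(0.8, 0.9, 0.1, 0.2), c(1, 1, 0, 0),
                      caliper_sd_fraction = 0.2)
  expect_identical(m0$n_matched, 0L)
  expect_identical(nrow(m0$pairs), 0L)

  expect_error(caliper_match(c(0.5, 0.5, 0.3), c(0, 0, 1)), "degenerate")
})

test_that("matching agrees with a reference greedy implementation", {
  for (seed in c(1, 23)) {
    set.seed(seed)
    n <- 100
    sc <- plogis(rnorm(n, 0, 0.8))
    ex <- rbinom(n, 1, sc)
    if (sum(ex) == 0 || sum(ex) == n) next
    ids <- sprintf("id%03d", seq_len(n))
    m <- caliper_match(sc, ex, ids = ids)
    ref <- greedy_match_reference(sc, ex, ids, m$caliper)
    if (is.null(ref)) {
      expect_identical(m$n_matched, 0L)
    } else {
      expect_identical(m$n_matched, nrow(ref))
      expect_identical(m$pairs$exposed_id, ref$exposed_id)
      expect_identical(m$pairs$unexposed_id, ref$unexposed_id)
    }
    # invariants: no reuse, bounded distances, bounded count
    expect_identical(anyDuplicated(c(m$pairs$exposed_id,
                                     m$pairs$unexposed_id)), 0L)
    expect_true(all(m$pairs$ps_distance <= m$caliper))
    expect_lte(m$n_matched, min(sum(ex), sum(1 - ex)))
    # determinism
    expect_identical(caliper_match(sc, ex, ids = ids)$pairs, m$pairs)
  }
})

test_that("the full matching pipeline yields a valid matched-pair cohort", {
  d <- make_covariate_table(400, seed = 47)
  set.seed(48)
  d$time <- rexp(400, exp(0.5 * d$size))
  d$event <- rbinom(400, 1, 0.8)
  d$time[d$event == 0] <- d$time[d$event == 0] + 0.1
  res <- ps_match_cohort(d, c("age", "size"))
  expect_s3_class(res$cohort, "pair_data")
  expect_identical(nrow(res$cohort), res$match$n_matched)
  counts <- tabulate_pairs(res$cohort)
  expect_identical(counts$n_total, res$match$n_matched)
  # matched exposed/unexposed score gaps honor the caliper
  ie <- match(res$match$pairs$exposed_id, d$subject_id)
  iu <- match(res$match$pairs$unexposed_id, d$subject_id)
  expect_true(all(abs(res$scores[ie] - res$scores[iu]) <= res$match$caliper))
})
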