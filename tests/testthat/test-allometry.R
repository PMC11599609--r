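# Scaling regressions, normalization, residuals, interaction test.

test_that("a noiseless power law is recovered exactly", {
  sa <- exp(seq(log(500), log(8000), length.out = 13))
  y <- 3.2 * sa^0.56
  fit <- fit_loglog(sa, y, "width")
  expect_equal(fit$slope, 0.56, tolerance = 1e-10)
  expect_lt(diff(fit$ci95), 1e-8)
  expect_equal(fit$n, 13L)
  # scale equivariance: multiplying y only moves the intercept
  fit2 <- fit_loglog(sa, 10 * y, "width")
  expect_equal(fit2$slope, fit$slope, tolerance = 1e-12)
  expect_equal(fit2$intercept, fit$intercept + log(10), tolerance = 1e-10)
})

test_that("log-log CI covers the true exponent at the nominal rate", {
  set.seed(42)
  sa <- exp(seq(log(500), log(8000), length.out = 13))
  hits <- replicate(500, {
    y <- sa^0.5 * exp(rnorm(13, 0, 0.1))
    ci <- fit_loglog(sa, y, "len")$ci95
    ci[1] <= 0.5 && 0.5 <= ci[2]
  })
  # Monte-Carlo: 95% coverage within binomial noise
  expect_gt(mean(hits), 0.92)
  expect_lt(mean(hits), 0.98)
})

test_that("non-positive values are rejected with the specimen named", {
  sa <- c(100, 200, 300)
  expect_error(fit_loglog(sa, c(1, -2, 3)), "2")
})

test_that("constant counts give a back-transformed slope of exactly 1", {
  sa <- c(500, 900, 1600, 2500, 4000)
  fit <- fit_scute_count(sa, rep(450L, 5))
  expect_equal(fit$slope, 1, tolerance = 1e-12)
  expect_error(fit_scute_count(sa, c(1.5, 2, 3, 4, 5)), "integer")
})

test_that("Poisson slope estimate is unbiased over replicates", {
  set.seed(7)
  sa <- seq(500, 5000, length.out = 13)
  b <- 1e-4
  est <- replicate(500, {
    counts <- rpois(13, exp(6 + b * sa))
    log(fit_scute_count(sa, counts, ci = "wald")$slope)
  })
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - b), 2 * se + 1e-7)
})

test_that("normalization by the fitted exponent flattens the relationship", {
  set.seed(3)
  sa <- exp(seq(log(500), log(8000), length.out = 13))
  y <- 0.4 * sa^-0.9 * exp(rnorm(13, 0, 0.15))
  fit <- fit_loglog(sa, y, "cgs")
  yn <- normalize_by_sa(y, sa, fit$slope)
  refit <- fit_loglog(sa, yn, "cgs_norm")
  expect_lt(abs(refit$slope), diff(fit$ci95))
  # trivial cases
  expect_identical(normalize_by_sa(5, 10, 0), 5)
  expect_equal(normalize_by_sa(3, 10, -1), 30)
})

test_that("residuals by geometry recover a planted class offset", {
  set.seed(11)
  classes <- rep(c("elliptic", "triangular", "tetragonal"), c(3, 5, 5))
  sa <- exp(runif(13, log(500), log(8000)))
  height <- sa^0.5 * exp(ifelse(classes == "elliptic", 0.3, 0)) *
    exp(rnorm(13, 0, 0.05))
  fit <- fit_loglog(sa, height, "height")
  rg <- residuals_by_geometry(fit, classes)
  expect_equal(sum(rg$residuals$residual), 0, tolerance = 1e-9)
  expect_identical(sum(rg$summary$n), 13L)
  med <- setNames(rg$summary$median, rg$summary$class)
  expect_gt(med["elliptic"], med["triangular"])
  expect_gt(med["elliptic"], med["tetragonal"])
  expect_error(residuals_by_geometry(fit, rep("round", 13)), "unknown")
})

test_that("interaction test keeps nominal size and detects real differences", {
  set.seed(5)
  sa <- exp(seq(log(500), log(8000), length.out = 13))
  p_null <- replicate(1000, {
    yf <- sa^0.5 * exp(rnorm(13, 0, 0.1))
    ye <- 2 * sa^0.5 * exp(rnorm(13, 0, 0.1))
    region_interaction_test(sa, yf, ye)
  })
  expect_lt(abs(mean(p_null < 0.05) - 0.05), 0.02)
  p_alt <- replicate(200, {
    yf <- sa^0.5 * exp(rnorm(13, 0, 0.1))
    ye <- sa^1.0 * exp(rnorm(13, 0, 0.1))
    region_interaction_test(sa, yf, ye)
  })
  expect_gt(mean(p_alt < 0.05), 0.5)
  # degenerate noiseless case: NA with warning
  expect_warning(p <- region_interaction_test(sa, sa^0.5, sa^0.5), "degenerate")
  expect_true(is.na(p))
})
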