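test_that("negative log-likelihood matches hand-evaluated two-point values", {
  # lambda = -2: -2*ln(1/0.9) + 2*ln(10)
  expect_equal(plb_negloglik(-2, c(1, 10), xmin = 1, xmax = 10),
               -2 * log(1 / 0.9) + 2 * log(10), tolerance = 1e-12)
  # lambda = -1: 2*ln(ln 10) + ln 10
  expect_equal(plb_negloglik(-1, c(1, 10), xmin = 1, xmax = 10),
               2 * log(log(10)) + log(10), tolerance = 1e-12)
})

test_that("likelihood is continuous across the removable singularity", {
  x <- c(1, 10)
  at_m1 <- plb_negloglik(-1, x, xmin = 1, xmax = 10)
  d <- vapply(c(1e-4, 1e-6, 1e-8), function(e) {
    max(abs(plb_negloglik(-1 + e, x, 1, 10) - at_m1),
        abs(plb_negloglik(-1 - e, x, 1, 10) - at_m1))
  }, numeric(1))
  expect_true(all(d < 1e-5))  # both branches join smoothly
})

test_that("likelihood rejects invalid inputs", {
  expect_error(plb_negloglik(-2, c(0.5, 10), xmin = 1, xmax = 10),
               "within")
  expect_error(plb_negloglik(-2, c(1, 10), xmin = 10, xmax = 1),
               "xmin < xmax")
})

test_that("quantile function inverts the CDF", {
  # closed-form check: lambda = -2, median is 1/0.55
  expect_equal(qplb(0.5, -2, 1, 10), 1 / 0.55, tolerance = 1e-12)
  expect_identical(qplb(0, -2, 1, 10), 1)
  expect_identical(qplb(1, -2, 1, 10), 10)
  expect_error(qplb(1.2, -2, 1, 10), "0, 1")
  params <- list(c(-2, 1, 10), c(-1, 0.5, 100), c(-1.5, 0.5, 64962),
                 c(0.5, 2, 20), c(-3.2, 1, 1e4))
  u <- seq(0, 1, length.out = 101)
  for (p in params) {
    back <- pplb(qplb(u, p[1], p[2], p[3]), p[1], p[2], p[3])
    expect_equal(back, u, tolerance = 1e-10)
  }
})

test_that("sampler respects support, is seed-reproducible and matches the CDF", {
  set.seed(99)
  x <- rplb(1e6, -2.3, 0.5, 64962)
  expect_true(all(x >= 0.5 & x <= 64962))
  set.seed(7); a <- rplb(100, -1.5, 1, 100)
  set.seed(7); b <- rplb(100, -1.5, 1, 100)
  expect_identical(a, b)
  set.seed(11)
  y <- rplb(1e4, -1.5, 0.5, 1000)
  ks <- suppressWarnings(
    stats::ks.test(y, function(q) pplb(q, -1.5, 0.5, 1000)))
  expect_gt(ks$p.value, 0.01)
})

test_that("MLE agrees with an exhaustive grid search", {
  set.seed(202)
  for (i in 1:5) {
    lam <- runif(1, -3, 0)
    x <- rplb(50, lam, 0.5, 500)
    fit <- fit_plb(x, min_n = 20)
    expect_lt(abs(fit$lambda - grid_search_lambda(x)), 1e-3)
  }
})

test_that("estimator recovers the exponent and refuses bad samples", {
  set.seed(4)
  x <- rplb(10000, -2, 0.5, 1000)
  fit <- fit_plb(x)
  expect_lt(abs(fit$lambda + 2), 0.05)
  expect_true(fit$converged)
  expect_true(fit$ci[1] <= fit$lambda && fit$lambda <= fit$ci[2])
  expect_error(fit_plb(rplb(19, -2, 1, 10), min_n = 20), "insufficient")
  expect_error(fit_plb(rep(5, 30)), "degenerate")
  expect_error(fit_plb(c(rep(1, 30), -2)), "positive")
})

test_that("exponent estimate is scale equivariant", {
  set.seed(5)
  x <- rplb(500, -1.7, 0.5, 2000)
  f1 <- fit_plb(x)
  f2 <- fit_plb(x * 1000, xmin = f1$xmin * 1000, xmax = f1$xmax * 1000)
  expect_lt(abs(f1$lambda - f2$lambda), 1e-6)
})

test_that("estimation error shrinks with sample size", {
  # consistency: RMSE over replicates decreases monotonically in n
  set.seed(606)
  for (lam in c(-2.5, -1.5, -0.5)) {
    rmse <- vapply(c(100, 1000, 10000), function(n) {
      err <- replicate(60, fit_plb(rplb(n, lam, 0.5, 1000))$lambda - lam)
      sqrt(mean(err^2))
    }, numeric(1))
    expect_true(all(diff(rmse) < 0))
  }
})

test_that("profile interval narrows with information and tracks the level", {
  set.seed(8)
  x_small <- rplb(1000, -1.5, 0.5, 1000)
  x_big <- rplb(100000, -1.5, 0.5, 1000)
  f_small <- fit_plb(x_small)
  f_big <- fit_plb(x_big)
  expect_lt(diff(f_big$ci), diff(f_small$ci))
  ci90 <- confint(f_small, level = 0.90)
  ci99 <- confint(f_small, level = 0.99)
  expect_lt(diff(as.numeric(ci90)), diff(f_small$ci))
  expect_gt(diff(as.numeric(ci99)), diff(f_small$ci))
})

test_that("plb_fit methods are coherent", {
  set.seed(10)
  fit <- fit_plb(rplb(200, -1.8, 1, 500))
  expect_named(coef(fit), "lambda")
  expect_equal(as.numeric(logLik(fit)), -fit$nll_min)
  sims <- simulate(fit, nsim = 2, seed = 3, n = 50)
  expect_identical(dim(sims), c(50L, 2L))
  expect_true(all(sims >= fit$xmin & sims <= fit$xmax))
  expect_lt(max(abs(residuals(fit))), 0.5)
  expect_output(print(summary(fit)), "PLB")
})

test_that("cutoff sensitivity is concordant when a single exponent rules", {
  set.seed(12)
  recs <- do.call(rbind, lapply(1:8, function(i) {
    lam <- runif(1, -2.2, -1.2)
    fr(survey = sprintf("S%d", i), mass = rplb(5000, lam, 0.5, 5000))
  }))
  out <- cutoff_sensitivity(recs, cutoffs = c(0.5, 1, 2, 3, 4), min_n = 20)
  expect_true(all(out$concordance >= 0.95))
  expect_equal(out$n_common, 8)
})

test_that("cutoff sensitivity drops emptied surveys and checks its input", {
  recs <- rbind(fr(survey = "A", mass = runif(100, 0.6, 5)),
                fr(survey = "B", mass = runif(100, 10, 500)))
  out <- suppressWarnings(
    cutoff_sensitivity(recs, cutoffs = c(0.5, 8), min_n = 20))
  expect_true(is.na(out$exponents["A", "cutoff_8"]))  # all of A is below 8 g
  expect_equal(unname(out$dropped["cutoff_8"]), 1)
  expect_error(cutoff_sensitivity(recs, cutoffs = c(4, 1)), "ascending")
})
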