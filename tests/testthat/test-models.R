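# a small reusable design built from generated data
suite_inputs <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      ds <- small_direct_dataset()
      filt <- filter_surveys(ds$records)
      memo <<- list(
        ds = ds,
        spectra = fit_spectra(filt$records),
        metrics = survey_metrics(filt$records, ds$effort, ds$covariates))
    }
    memo
  }
})

test_that("design preparation applies the documented transforms and scaling", {
  si <- suite_inputs()
  design <- suppressMessages(
    prepare_design(si$metrics, si$spectra, si$ds$covariates,
                   "exponent_native"))
  cont <- attr(design, "continuous_terms")
  for (v in cont) {
    expect_lt(abs(mean(design[[v]])), 1e-10)
    expect_equal(sd(design[[v]]), 1, tolerance = 1e-10)
  }
  expect_lt(abs(mean(design$y)), 1e-10)
  # square-root transform of the dominance shares before scaling:
  # the design column must be a linear map of sqrt(raw), not of raw
  raw <- si$metrics$pisc_nn[match(design$survey_id, si$metrics$survey_id)]
  expect_equal(cor(design$pisc_nn, sqrt(raw)), 1, tolerance = 1e-12)
  if (sd(raw) > 0 && cor(sqrt(raw), raw) < 0.9999) {
    expect_lt(cor(design$pisc_nn, raw), 1)
  }
  # reference levels documented: natural lakes are the baseline
  expect_identical(levels(design$lake_type)[1], "natural")
})

test_that("VIFs match the auxiliary-regression oracle and flag collinearity", {
  # mutually orthogonal predictors -> all VIF = 1
  X <- data.frame(a = rep(c(-1, 1), 8),
                  b = rep(c(-1, -1, 1, 1), 4),
                  c = rep(c(-1, 1, 1, -1), 4))
  v <- check_vif(X, terms = c("a", "b", "c"))
  expect_equal(v$vif, rep(1, 3), tolerance = 1e-8)
  expect_true(all(v$flag == "ok"))

  # brute-force oracle 1/(1 - R^2) on a correlated 3-variable fixture
  set.seed(33)
  Y <- data.frame(a = rnorm(100))
  Y$b <- 0.6 * Y$a + rnorm(100)
  Y$c <- -0.3 * Y$a + 0.5 * Y$b + rnorm(100)
  v2 <- check_vif(Y, terms = c("a", "b", "c"))
  oracle <- vapply(c("a", "b", "c"), function(t) {
    r2 <- summary(lm(stats::reformulate(setdiff(c("a", "b", "c"), t), t),
                     data = Y))$r.squared
    1 / (1 - r2)
  }, numeric(1))
  expect_equal(v2$vif, unname(oracle), tolerance = 1e-8)

  # near-duplicate columns blow up and get flagged
  Z <- data.frame(x1 = rnorm(50))
  Z$x2 <- Z$x1 + rnorm(50, 0, 1e-4)
  v3 <- check_vif(Z, terms = c("x1", "x2"))
  expect_true(all(v3$vif > 4))
  expect_true(all(v3$flag != "ok"))
})

test_that("mixed fit degenerates to OLS with one survey per lake", {
  set.seed(44)
  n <- 120
  design <- data.frame(y = rnorm(n), x = rnorm(n),
                       z = rnorm(n), lake_id = factor(seq_len(n)))
  f <- suppressMessages(suppressWarnings(
    fit_mixed(design, y ~ x + z + (1 | lake_id))))
  ols <- coef(lm(y ~ x + z, data = design))
  expect_equal(unname(coef(f)[names(ols)]), unname(ols), tolerance = 1e-6)
})

test_that("zero lake-level variance is flagged, never hidden", {
  # with no lake effect the REML estimate sits at or near the boundary;
  # whenever it hits zero the singularity must be flagged
  hit_boundary <- FALSE
  for (s in 1:5) {
    set.seed(s)
    lake <- factor(rep(1:50, each = 4))
    x <- rnorm(200)
    design <- data.frame(y = 0.4 * x + rnorm(200), x = x, lake_id = lake)
    f <- suppressMessages(fit_mixed(design, y ~ x + (1 | lake_id)))
    expect_lt(f$variance_components[["lake"]], 0.2)
    if (f$variance_components[["lake"]] < 1e-4) {
      hit_boundary <- TRUE
      expect_true("singular_random_effect" %in% f$flags)
    }
  }
  expect_true(hit_boundary)
})

test_that("mixed fit recovers known variance components", {
  set.seed(45)
  n_lakes <- 200
  per <- 5
  lake <- factor(rep(seq_len(n_lakes), each = per))
  re <- rnorm(n_lakes, 0, 1)
  x <- rnorm(n_lakes * per)
  y <- 0.5 * x + re[as.integer(lake)] + rnorm(n_lakes * per, 0, 1)
  design <- data.frame(y = y, x = x, lake_id = lake)
  f <- fit_mixed(design, y ~ x + (1 | lake_id))
  expect_lt(abs(f$variance_components[["lake"]] - 1), 0.2)
  expect_lt(abs(f$variance_components[["residual"]] - 1), 0.2)
  expect_lt(abs(unname(coef(f)["x"]) - 0.5), 0.1)
  expect_gt(f$r2_conditional, f$r2_marginal)
})

test_that("robust fit agrees with OLS on clean data, resists contamination", {
  set.seed(46)
  n <- 500
  x <- rnorm(n)
  design <- data.frame(y = 1 + 0.8 * x + rnorm(n, 0, 0.3), x = x,
                       lake_id = factor(rep(1:50, 10)))
  fr_ <- fit_robust(design, y ~ x)
  ols <- summary(lm(y ~ x, data = design))$coefficients
  expect_lt(abs(coef(fr_)["x"] - ols["x", "Estimate"]),
            2 * ols["x", "Std. Error"])

  # 5% gross outliers at high leverage: response +10 sd
  bad <- order(x, decreasing = TRUE)[seq_len(n * 0.05)]
  design$y[bad] <- design$y[bad] + 10 * sd(design$y)
  frob <- fit_robust(design, y ~ x)
  ls2 <- coef(lm(y ~ x, data = design))
  expect_lt(abs(coef(frob)["x"] - 0.8), 0.05)
  expect_gt(abs(ls2["x"] - 0.8), 0.2)
})

test_that("rank-deficient robust designs fail loudly naming the alias", {
  set.seed(47)
  design <- data.frame(y = rnorm(30), x1 = rnorm(30))
  design$x2 <- design$x1
  expect_error(fit_robust(design, y ~ x1 + x2), "x2")
})

test_that("the four-model suite fits all specifications with sane output", {
  si <- suite_inputs()
  suite <- suppressMessages(suppressWarnings(
    run_model_suite(si$metrics, si$spectra, si$ds$covariates)))
  expect_named(suite$models, c("exponent_all", "biomass_all",
                               "exponent_native", "biomass_native"))
  expect_identical(suite$models$exponent_all$estimator, "robust")
  expect_identical(suite$models$biomass_all$estimator, "mixed")
  expect_true(all(suite$coefficients$p_value >= 0 &
                    suite$coefficients$p_value <= 1, na.rm = TRUE))
  # interaction terms carry their main effects
  terms_all <- suite$models$exponent_all$coefficients$term
  expect_true(all(c("pca_inv", "temp", "pca_inv:temp") %in% terms_all))
  terms_nat <- suite$models$exponent_native$coefficients$term
  expect_true(all(c("pisc_nn", "ltl_nn", "pisc_nn:temp", "ltl_nn:temp")
                  %in% terms_nat))
})

test_that("dropping dataset_type leaves key exponent estimates stable", {
  si <- suite_inputs()
  design <- suppressMessages(
    prepare_design(si$metrics, si$spectra, si$ds$covariates, "exponent_all"))
  full <- fit_robust(design)
  reduced <- fit_robust(design, y ~ pca_inv * temp + totP + precip_axis +
                          lake_area + max_depth + sp_rich + lake_type)
  for (term in c("pca_inv", "pca_inv:temp")) {
    b_full <- full$coefficients[full$coefficients$term == term, ]
    b_red <- reduced$coefficients[reduced$coefficients$term == term, ]
    expect_identical(sign(b_full$beta), sign(b_red$beta))
    expect_identical(b_full$p_value < 0.05, b_red$p_value < 0.05)
  }
})
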