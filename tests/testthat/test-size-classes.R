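test_that("computed grid follows the closed-form log-spaced edges", {
  g <- build_size_class_grid(c(0.5, 64962), k = 10)
  expect_length(g$edges, 11)
  expect_equal(g$edges[1], 0.5)
  expect_equal(g$edges[11], 64962)
  # first interior edge: 0.5 * (64962/0.5)^(1/10)
  expect_equal(g$edges[2], 1.623076, tolerance = 1e-6)
  # constant edge ratio on the log scale
  ratios <- g$edges[-1] / g$edges[-11]
  expect_lt(max(abs(ratios - ratios[1])), 1e-12)
})

test_that("explicit grids are validated and used verbatim", {
  g <- build_size_class_grid(explicit_edges = reference_class_edges)
  expect_identical(g$construction, "explicit")
  expect_equal(g$edges[3:4], c(4.42, 13.14))  # Class3 bounds
  expect_error(build_size_class_grid(explicit_edges = c(1, 3, 2)),
               "increasing")
  expect_error(build_size_class_grid(rep(2, 5), k = 10), "degenerate")
  expect_error(build_size_class_grid(c(1, 2), k = 1), "k >= 2")
})

test_that("class biomass sums natives per bin with log1p transform", {
  g <- build_size_class_grid(explicit_edges = reference_class_edges)
  recs <- rbind(
    fr(survey = "A", mass = rep(5, 7), status = "native"),
    fr(survey = "A", mass = 5000, status = "non_native"),
    fr(survey = "B", mass = c(10, 1000), status = "native"),
    fr(survey = "C", mass = c(2, 3), status = "non_native"))
  mat <- native_biomass_by_class(recs, g)
  # survey A: all native mass (35 g) in Class3; the non-native is ignored
  expect_equal(unname(mat["A", ]), c(0, 0, log1p(35), rep(0, 7)))
  # survey B: exactly ln(11) and ln(1001) in their classes
  expect_equal(sort(mat["B", mat["B", ] > 0]),
               unname(sort(c(log(11), log(1001)))), ignore_attr = TRUE)
  # survey C has no natives: all-zero row
  expect_equal(unname(mat["C", ]), rep(0, 10))
  # mass outside the grid is an error
  expect_error(
    native_biomass_by_class(fr(survey = "D", mass = 0.1, status = "native"),
                            g), "outside")
})

test_that("class biomass conserves the native total per survey", {
  ds <- small_direct_dataset()
  filt <- filter_surveys(ds$records)
  g <- build_size_class_grid(filt$records$body_mass_g, k = 10)
  mat <- native_biomass_by_class(filt$records, g)
  raw <- attr(mat, "raw")
  nat <- filt$records[filt$records$origin_status == "native", ]
  totals <- tapply(nat$body_mass_g, nat$survey_id, sum)
  expect_equal(unname(rowSums(raw)[names(totals)]), as.numeric(totals),
               tolerance = 1e-9)
})

test_that("dominance correlations match a midrank oracle and flag ties", {
  # 6-survey fixture: compute Spearman rho by explicit midranks
  mat <- matrix(c(5, 3, 8, 1, 9, 4), ncol = 1,
                dimnames = list(paste0("S", 1:6), "class_1"))
  mat <- cbind(mat, class_2 = c(2, 2, 2, 2, 2, 2))
  attr(mat, "edges") <- c(1, 10, 100)
  metrics <- data.frame(survey_id = paste0("S", 1:6),
                        pisc_nn = c(0.1, 0.2, 0.2, 0.5, 0.05, 0.3),
                        ltl_nn = c(0.3, 0.1, 0.4, 0.2, 0.6, 0.15))
  out <- class_dominance_correlations(mat, metrics)
  oracle <- function(a, b) stats::cor(rank(a), rank(b))  # midrank Pearson
  got <- out$rho[out$predictor == "pisc_nn" & out$class == 1]
  expect_equal(got, oracle(metrics$pisc_nn, mat[, 1]))
  # constant class: undefined, flagged missing rather than zero
  flagged <- out[out$class == 2, ]
  expect_true(all(is.na(flagged$rho)))
  expect_true(all(flagged$flag == "zero_variance"))
})

test_that("rank correlations are invariant to monotone predictor transforms", {
  set.seed(14)
  mat <- matrix(rlnorm(40), nrow = 10,
                dimnames = list(paste0("S", 1:10), paste0("class_", 1:4)))
  attr(mat, "edges") <- c(1, 2, 4, 8, 16)
  metrics <- data.frame(survey_id = paste0("S", 1:10),
                        pisc_nn = runif(10), ltl_nn = runif(10))
  out1 <- class_dominance_correlations(mat, metrics)
  metrics2 <- metrics
  metrics2$pisc_nn <- sqrt(metrics2$pisc_nn)
  metrics2$ltl_nn <- sqrt(metrics2$ltl_nn)
  out2 <- class_dominance_correlations(mat, metrics2)
  expect_equal(out1$rho, out2$rho)
  expect_equal(out1$p_value, out2$p_value)
})

test_that("perfect monotone decline gives rho = -1", {
  mat <- matrix(c(10, 8, 6, 4, 2), ncol = 1,
                dimnames = list(paste0("S", 1:5), "class_1"))
  mat <- cbind(mat, class_2 = c(1, 2, 3, 4, 5))
  attr(mat, "edges") <- c(1, 10, 100)
  metrics <- data.frame(survey_id = paste0("S", 1:5),
                        pisc_nn = seq(0.1, 0.5, 0.1),
                        ltl_nn = seq(0.1, 0.5, 0.1))
  out <- class_dominance_correlations(mat, metrics)
  expect_equal(out$rho[out$class == 1 & out$predictor == "ltl_nn"], -1)
  expect_equal(out$rho[out$class == 2 & out$predictor == "ltl_nn"], 1)
})
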