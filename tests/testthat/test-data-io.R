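test_that("well-formed tables round-trip through disk losslessly", {
  ds <- small_direct_dataset()
  tmp <- withr::local_tempdir()
  write_fish_records(ds$records, file.path(tmp, "fish.csv"))
  write_survey_effort(ds$effort, file.path(tmp, "effort.csv"))
  write_lake_covariates(ds$covariates, file.path(tmp, "cov.csv"))
  rec2 <- read_fish_records(file.path(tmp, "fish.csv"))
  eff2 <- read_survey_effort(file.path(tmp, "effort.csv"))
  cov2 <- read_lake_covariates(file.path(tmp, "cov.csv"))
  expect_equal(rec2, ds$records[, names(rec2)], ignore_attr = TRUE)
  expect_equal(eff2, ds$effort[, names(eff2)], ignore_attr = TRUE)
  expect_equal(cov2, ds$covariates[, names(cov2)], ignore_attr = TRUE)
})

test_that("schema and enumeration violations are reported, not dropped", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  bad <- fr(mass = c(10, 20, 30))
  utils::write.csv(bad[, -which(names(bad) == "trophic_guild")], tmp,
                   row.names = FALSE)
  expect_error(read_fish_records(tmp), "trophic_guild")

  bad2 <- fr(mass = c(10, 20), guild = c("omnivore", "parasite"))
  utils::write.csv(bad2, tmp, row.names = FALSE)
  expect_error(read_fish_records(tmp), "parasite")

  expect_error(validate_fish_records(fr(mass = -1)), "body_mass_g")
  expect_error(validate_survey_effort(
    data.frame(survey_id = c("A", "A"), lake_id = "L1", date = "2020-01-01",
               net_area_km2 = 0.001, duration_h = 12)), "duplicated")
})

test_that("length-weight fit recovers exact and noisy allometries", {
  # noiseless power-law data recovers (a, b) to machine precision
  for (p in list(c(0.01, 3), c(0.02, 2.8), c(0.005, 3.3))) {
    len <- seq(5, 60, length.out = 15)
    recs <- fr(mass = p[1] * len^p[2], length = len, species = "spX")
    m <- fit_length_weight(recs, "spX")
    expect_true(m$available)
    expect_equal(m$a, p[1], tolerance = 1e-8)
    expect_equal(m$b, p[2], tolerance = 1e-8)
  }
  # too few complete records
  few <- fr(mass = c(10, 20), length = c(10, 14), species = "spY")
  expect_false(fit_length_weight(few, "spY", min_fit = 5)$available)
  # noisy simulated allometry
  set.seed(21)
  len <- runif(200, 4, 80)
  noisy <- fr(mass = 0.01 * len^3.1 * rlnorm(200, 0, 0.1), length = len,
              species = "spZ")
  m <- fit_length_weight(noisy, "spZ")
  expect_lt(abs(m$b - 3.1), 0.05)
})

test_that("mass imputation follows the three-tier rule with provenance", {
  len <- seq(5, 40, length.out = 12)
  base <- fr(mass = 0.01 * len^3, length = len, species = "spA",
             survey = "S1")
  extra <- fr(mass = c(NA, NA, NA), length = c(10, NA, NA),
              species = c("spA", "spB", "spC"), survey = "S1")
  extra$body_mass_g[2] <- NA
  pool_b <- fr(mass = c(5, 5, 5), species = "spB", survey = "S1")
  recs <- rbind(base, extra, pool_b)
  out <- suppressMessages(impute_missing_mass(recs, seed = 3))
  # measured records untouched
  expect_equal(out$body_mass_g[1:12], base$body_mass_g)
  expect_true(all(out$mass_provenance[1:12] == "measured"))
  # length 10, a = 0.01, b = 3 -> 10 g
  iA <- which(out$species_id == "spA" & out$mass_provenance != "measured")
  expect_equal(out$body_mass_g[iA], 10, tolerance = 1e-8)
  expect_equal(out$mass_provenance[iA], "length_weight")
  # degenerate conspecific pool {5,5,5} -> 5 g
  iB <- which(out$species_id == "spB" & out$mass_provenance != "measured")
  expect_equal(out$body_mass_g[iB], 5)
  expect_equal(out$mass_provenance[iB], "empirical_draw")
  # spC has neither data nor conspecifics: dropped and counted
  expect_false("spC" %in% out$species_id)
  expect_equal(attr(out, "n_unresolved"), 1)
  expect_true(all(out$body_mass_g > 0))
})

test_that("survey filter enforces size and composition rules", {
  recs <- rbind(
    fr(survey = "small", mass = 1:19,
       status = rep(c("native", "non_native"), length.out = 19),
       species = rep(c("a", "b", "c"), length.out = 19)),
    fr(survey = "allnat", mass = 1:50, status = "native",
       species = rep(c("a", "b"), 25)),
    fr(survey = "good", mass = 1:25,
       status = rep(c("native", "non_native"), length.out = 25),
       species = rep(c("a", "b"), length.out = 25)))
  out <- filter_surveys(recs)
  expect_identical(out$retained, "good")
  expect_true(all(c("too_few_individuals", "no_nonnative_species") %in%
                    out$report$reason))
  expect_identical(
    out$report$reason[out$report$survey_id == "small"],
    "too_few_individuals")
  # idempotence: filtering the retained records changes nothing
  again <- filter_surveys(out$records)
  expect_identical(again$retained, out$retained)
  expect_identical(nrow(again$report), 0L)
  # empty input warns
  expect_warning(filter_surveys(recs[0, ]), "empty")
})

test_that("generated datasets pass validation and retain nearly all surveys", {
  cfg <- generator_config(seed = 31)  # default study-scale conditions
  ds <- generate_direct(cfg)
  expect_silent(validate_fish_records(ds$records))
  filt <- filter_surveys(ds$records)
  expect_gte(length(filt$retained) / nrow(ds$effort), 0.95)
  # imputation leaves no undefined mass among retained surveys
  imp <- impute_missing_mass(filt$records, ds$covariates, seed = 1)
  expect_false(anyNA(imp$body_mass_g))
})
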