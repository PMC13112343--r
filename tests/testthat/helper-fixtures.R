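# small in-code fixtures and independent oracles shared across tests

# build a fish-record table from parallel vectors, recycling as needed
fr <- function(survey = "S1", lake = "L1", species = "sp1", mass = 10,
               length = NA_real_, status = "native", guild = "omnivore") {
  n <- max(lengths(list(survey, lake, species, mass, length, status, guild)))
  data.frame(survey_id = rep_len(survey, n), lake_id = rep_len(lake, n),
             species_id = rep_len(species, n),
             total_length_cm = rep_len(length, n),
             body_mass_g = rep_len(mass, n),
             origin_status = rep_len(status, n),
             trophic_guild = rep_len(guild, n))
}

# independent brute-force PLB MLE: exhaustive grid search with its own
# vectorised likelihood (never calls the package's optimiser)
grid_search_lambda <- function(x, step = 1e-4, range = c(-6, 3)) {
  lams <- seq(range[1], range[2], by = step)
  n <- length(x)
  slx <- sum(log(x))
  xmin <- min(x)
  xmax <- max(x)
  l1 <- lams + 1
  nll <- ifelse(
    abs(l1) < 1e-12,
    n * log(log(xmax) - log(xmin)) + slx,
    -n * log(l1 / (xmax^l1 - xmin^l1)) - lams * slx)
  lams[which.min(nll)]
}

# the published 10-class grid used as the explicit-edges reference
reference_class_edges <- c(0.5, 1.49, 4.42, 13.14, 39.08, 116.19, 345.47,
                           1027.18, 3054.11, 9080.8, 64962)

# a small direct-mode dataset reused by several test files
small_direct_dataset <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      cfg <- generator_config(n_lakes = 40, surveys_per_lake = c(1, 3),
                              n_fish_per_survey = c(60, 200), seed = 42)
      memo <<- generate_direct(cfg)
    }
    memo
  }
})
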