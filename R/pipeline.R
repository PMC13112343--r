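#' Run the full size-spectrum analysis pipeline
#'
#' Orchestrates every stage on one dataset: validation and mass
#' imputation, survey-inclusion filtering, per-survey PLB spectrum fits
#' (whole community and native only), survey metrics with the
#' invasion-pressure and precipitation axes, the logarithmic size-class
#' biomass correlations, the four-model inference suite, and (optional)
#' the 4 g minimum-mass sensitivity refit and the cutoff concordance
#' table.
#'
#' @param records,effort,covariates the three input tables (validated
#'   data frames, e.g. from [read_fish_records()] or a
#'   `"synthetic_dataset"`'s components). Alternatively pass a
#'   `"synthetic_dataset"` as `records` and leave the others `NULL`.
#' @param min_individuals survey-inclusion threshold (default 20).
#' @param cutoffs minimum-mass cutoffs (g) for the concordance analysis;
#'   `NULL` skips it.
#' @param size_class_k number of logarithmic size classes.
#' @param size_class_edges optional explicit grid edges (overrides the
#'   computed grid).
#' @param run_models fit the four-model suite?
#' @param cutoff4_refit also refit the exponent models on 4 g-cutoff
#'   spectra?
#' @param seed integer seed covering the stochastic imputation branch.
#' @param out_dir optional directory; when given, every output table is
#'   written there as delimited text together with a manifest.
#' @return an object of class `"spectrum_pipeline"`: list with
#'   `spectra`, `metrics`, `grid`, `class_biomass`,
#'   `class_correlations`, `models` (a `"spectrum_model_suite"` or
#'   NULL), `sensitivity` (cutoff concordance or NULL), `exclusions`,
#'   `retained`, and `settings`.
#' @export
run_pipeline <- function(records, effort = NULL, covariates = NULL,
                         min_individuals = 20,
                         cutoffs = NULL,
                         size_class_k = 10, size_class_edges = NULL,
                         run_models = TRUE, cutoff4_refit = FALSE,
                         seed = 1L, out_dir = NULL) {
  if (inherits(records, "synthetic_dataset")) {
    effort <- records$effort
    covariates <- records$covariates
    records <- records$records
  }
  records <- validate_fish_records(records)
  effort <- validate_survey_effort(effort)
  covariates <- validate_lake_covariates(covariates)

  records <- impute_missing_mass(records, covariates, seed = seed)
  filt <- filter_surveys(records, min_individuals)
  kept <- filt$records

  spectra <- fit_spectra(kept, min_n = min_individuals)
  metrics <- survey_metrics(kept, effort, covariates)

  grid <- build_size_class_grid(kept$body_mass_g, k = size_class_k,
                                explicit_edges = size_class_edges)
  class_biomass <- native_biomass_by_class(kept, grid)
  class_cor <- class_dominance_correlations(class_biomass, metrics)

  models <- NULL
  if (run_models) {
    cutoff_spectra <- NULL
    if (cutoff4_refit) {
      trunc4 <- kept[kept$body_mass_g >= 4, , drop = FALSE]
      cutoff_spectra <- fit_spectra(trunc4, min_n = min_individuals)
    }
    models <- run_model_suite(metrics, spectra, covariates,
                              cutoff_spectra = cutoff_spectra)
  }

  sensitivity <- if (!is.null(cutoffs)) {
    cutoff_sensitivity(kept, cutoffs, min_n = min_individuals)
  }

  out <- structure(
    list(spectra = spectra, metrics = metrics, grid = grid,
         class_biomass = class_biomass, class_correlations = class_cor,
         models = models, sensitivity = sensitivity,
         exclusions = filt$report, retained = filt$retained,
         settings = list(min_individuals = min_individuals,
                         cutoffs = cutoffs, size_class_k = size_class_k,
                         size_class_edges = size_class_edges,
                         cutoff4_refit = cutoff4_refit, seed = seed)),
    class = "spectrum_pipeline")
  if (!is.null(out_dir)) write_pipeline_bundle(out, out_dir)
  out
}

#' @export
print.spectrum_pipeline <- function(x, ...) {
  cat("size-spectrum pipeline result\n")
  cat(sprintf("  %d surveys retained (%d excluded)\n",
              length(x$retained), length(unique(x$exclusions$survey_id))))
  cat(sprintf("  mean exponent: all = %.3f, native = %.3f\n",
              mean(x$spectra$lambda_hat, na.rm = TRUE),
              mean(x$spectra$lambda_hat_native, na.rm = TRUE)))
  cat(sprintf("  invasion axis explains %.1f%% of variance\n",
              100 * attr(x$metrics, "pca_inv_var")))
  if (!is.null(x$models)) {
    cat(sprintf("  model suite: %d models fitted\n",
                length(x$models$models)))
  }
  invisible(x)
}

#' Write a pipeline results bundle
#'
#' Writes every output table of a [run_pipeline()] result as delimited
#' text in one directory, plus a `manifest.txt` listing the artifacts
#' and the settings used.
#'
#' @param result a `"spectrum_pipeline"`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_pipeline_bundle <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
    name
  }
  files <- c(
    wr(result$spectra, "exponents.csv"),
    wr(result$metrics, "survey_metrics.csv"),
    wr(data.frame(edge_g = result$grid$edges), "size_class_edges.csv"),
    wr(data.frame(survey_id = rownames(result$class_biomass),
                  result$class_biomass, check.names = FALSE),
       "class_biomass.csv"),
    wr(result$class_correlations, "class_correlations.csv"),
    wr(result$exclusions, "exclusions.csv"))
  if (!is.null(result$models)) {
    files <- c(files, wr(result$models$coefficients, "model_coefficients.csv"))
  }
  if (!is.null(result$sensitivity)) {
    files <- c(files,
               wr(as.data.frame(result$sensitivity$exponents),
                  "cutoff_exponents.csv"),
               wr(as.data.frame(result$sensitivity$concordance),
                  "cutoff_concordance.csv"))
  }
  settings <- result$settings
  manifest <- c("size-spectrum pipeline bundle", "files:",
                paste(" -", files), "settings:",
                paste("  ", names(settings), "=",
                      vapply(settings, function(s) {
                        paste(format(s), collapse = ",")
                      }, character(1))))
  writeLines(manifest, file.path(dir, "manifest.txt"))
  invisible(dir)
}
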