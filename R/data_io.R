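#' @keywords internal
"_PACKAGE"

# enumerations of the data model
.origin_levels <- c("native", "non_native")
.guild_levels <- c("piscivore", "omnivore", "detritivore", "herbivore",
                   "invertivore")
.lake_type_levels <- c("natural", "artificial")

.fish_cols <- c("survey_id", "lake_id", "species_id", "total_length_cm",
                "body_mass_g", "origin_status", "trophic_guild")
.effort_cols <- c("survey_id", "lake_id", "date", "net_area_km2",
                  "duration_h")
.cov_cols <- c("lake_id", "temp_c", "totp_ugL", "precip_monthly_mm",
               "precip_relative", "lake_area_km2", "max_depth_m",
               "lake_type", "dataset_type")

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing mandatory column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

check_levels <- function(values, levels, what, column) {
  bad <- which(!is.na(values) & !(values %in% levels))
  if (length(bad)) {
    labs <- unique(values[bad])
    stop(sprintf("%s: unknown %s label(s) %s (rows %s)", what, column,
                 paste(sQuote(labs), collapse = ", "),
                 paste(utils::head(bad, 10), collapse = ", ")),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Read and validate the three pipeline input tables
#'
#' The pipeline consumes three delimited text files (comma-separated,
#' header row, UTF-8): individual fish records (one row per fish),
#' per-survey gillnet effort, and per-lake covariates. These readers
#' validate the column schema, the status/guild/lake-type enumerations
#' and the positivity constraints, and fail loudly (naming the offending
#' column or rows) rather than silently dropping data.
#'
#' Expected columns:
#' * fish records: `survey_id`, `lake_id`, `species_id`,
#'   `total_length_cm` (may be NA), `body_mass_g` (may be NA before
#'   imputation), `origin_status` (`native`/`non_native`),
#'   `trophic_guild` (`piscivore`/`omnivore`/`detritivore`/`herbivore`/
#'   `invertivore`).
#' * survey effort: `survey_id`, `lake_id`, `date` (ISO-8601),
#'   `net_area_km2` (> 0), `duration_h` (> 0); one row per survey.
#' * lake covariates: `lake_id`, `temp_c` (mean annual air temperature),
#'   `totp_ugL`, `precip_monthly_mm`, `precip_relative`,
#'   `lake_area_km2`, `max_depth_m`, `lake_type`
#'   (`natural`/`artificial`), `dataset_type`; one row per lake.
#'
#' @param path path to a delimited text file.
#' @return a validated data frame with the documented columns.
#' @seealso [validate_fish_records()], [write_fish_records()]
#' @export
read_fish_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_fish_records(df)
}

#' @rdname read_fish_records
#' @export
read_survey_effort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_survey_effort(df)
}

#' @rdname read_fish_records
#' @export
read_lake_covariates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_lake_covariates(df)
}

#' Validate in-memory pipeline tables
#'
#' The same schema and invariant checks as the file readers, applied to
#' data frames already in memory (e.g. generator output).
#'
#' @param records,effort,covariates data frames in the documented schema
#'   (see [read_fish_records()]).
#' @return the validated data frame, invisibly unchanged apart from
#'   column order.
#' @export
validate_fish_records <- function(records) {
  check_columns(records, .fish_cols, "fish_records")
  check_levels(records$origin_status, .origin_levels, "fish_records",
               "origin_status")
  check_levels(records$trophic_guild, .guild_levels, "fish_records",
               "trophic_guild")
  bad_len <- which(!is.na(records$total_length_cm) &
                     records$total_length_cm <= 0)
  if (length(bad_len)) {
    stop(sprintf("fish_records: non-positive total_length_cm (rows %s)",
                 paste(utils::head(bad_len, 10), collapse = ", ")),
         call. = FALSE)
  }
  bad_mass <- which(!is.na(records$body_mass_g) & records$body_mass_g <= 0)
  if (length(bad_mass)) {
    stop(sprintf("fish_records: non-positive body_mass_g (rows %s)",
                 paste(utils::head(bad_mass, 10), collapse = ", ")),
         call. = FALSE)
  }
  records[, union(.fish_cols, names(records))]
}

#' @rdname validate_fish_records
#' @export
validate_survey_effort <- function(effort) {
  check_columns(effort, .effort_cols, "survey_effort")
  if (anyDuplicated(effort$survey_id)) {
    stop("survey_effort: duplicated survey_id", call. = FALSE)
  }
  if (any(effort$net_area_km2 <= 0 | effort$duration_h <= 0, na.rm = TRUE)) {
    stop("survey_effort: net_area_km2 and duration_h must be > 0",
         call. = FALSE)
  }
  effort[, union(.effort_cols, names(effort))]
}

#' @rdname validate_fish_records
#' @export
validate_lake_covariates <- function(covariates) {
  check_columns(covariates, .cov_cols, "lake_covariates")
  if (anyDuplicated(covariates$lake_id)) {
    stop("lake_covariates: duplicated lake_id", call. = FALSE)
  }
  check_levels(covariates$lake_type, .lake_type_levels, "lake_covariates",
               "lake_type")
  if (any(covariates$lake_area_km2 <= 0 | covariates$max_depth_m <= 0,
          na.rm = TRUE)) {
    stop("lake_covariates: lake_area_km2 and max_depth_m must be > 0",
         call. = FALSE)
  }
  covariates[, union(.cov_cols, names(covariates))]
}

#' Write pipeline tables as delimited text
#'
#' @param x a validated table.
#' @param path output file path (comma-separated, header row).
#' @return `path`, invisibly.
#' @export
write_fish_records <- function(x, path) {
  utils::write.csv(x[, .fish_cols], path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_fish_records
#' @export
write_survey_effort <- function(x, path) {
  utils::write.csv(x[, .effort_cols], path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_fish_records
#' @export
write_lake_covariates <- function(x, path) {
  utils::write.csv(x[, .cov_cols], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Species length-weight relationship
#'
#' Fits the standard allometry `mass = a * length^b` by least squares on
#' the log-log scale, `ln(mass) = ln(a) + b * ln(length)`, over the
#' records of one species that carry both a length and a mass.
#'
#' @param records fish-record table.
#' @param species species identifier; `NULL` pools all species (the
#'   fallback model for data-poor species).
#' @param min_fit minimum number of complete records required for a fit
#'   (default 10 — a two-parameter log-log regression on fewer points is
#'   too unstable to impute from).
#' @return an object of class `"lw_model"`: list with `species_id`, `a`
#'   (g cm^-b), `b`, `n_fit`, `available`. When fewer than `min_fit`
#'   complete records exist, `available` is `FALSE` and `a`, `b` are NA
#'   (the caller falls back to a pooled fit or an empirical draw).
#' @export
fit_length_weight <- function(records, species = NULL, min_fit = 10) {
  sub <- records
  if (!is.null(species)) sub <- sub[sub$species_id == species, , drop = FALSE]
  ok <- !is.na(sub$total_length_cm) & !is.na(sub$body_mass_g) &
    sub$total_length_cm > 0 & sub$body_mass_g > 0
  sub <- sub[ok, , drop = FALSE]
  n_fit <- nrow(sub)
  if (n_fit < min_fit || length(unique(sub$total_length_cm)) < 2) {
    return(structure(list(species_id = species, a = NA_real_, b = NA_real_,
                          n_fit = n_fit, available = FALSE),
                     class = "lw_model"))
  }
  fit <- stats::lm(log(body_mass_g) ~ log(total_length_cm), data = sub)
  cf <- stats::coef(fit)
  structure(list(species_id = species, a = exp(unname(cf[1])),
                 b = unname(cf[2]), n_fit = n_fit, available = TRUE),
            class = "lw_model")
}

#' @export
print.lw_model <- function(x, ...) {
  if (x$available) {
    cat(sprintf("length-weight model%s: mass = %.4g * length^%.4g (n = %d)\n",
                if (is.null(x$species_id)) " (pooled)"
                else paste0(" [", x$species_id, "]"),
                x$a, x$b, x$n_fit))
  } else {
    cat(sprintf("length-weight model: unavailable (n = %d complete records)\n",
                x$n_fit))
  }
  invisible(x)
}

#' Predict mass from length under a length-weight model
#'
#' @param object an available `lw_model`.
#' @param newdata numeric vector of total lengths (cm), or a data frame
#'   with a `total_length_cm` column.
#' @param ... unused.
#' @return predicted body masses (g), `a * length^b`.
#' @export
predict.lw_model <- function(object, newdata, ...) {
  if (!object$available) stop("length-weight model unavailable", call. = FALSE)
  len <- if (is.data.frame(newdata)) newdata$total_length_cm else newdata
  object$a * len^object$b
}

#' Impute missing body masses
#'
#' Applies the three-tier imputation rule to a fish-record table:
#' records with a measured mass are untouched; records with a length but
#' no mass get the species length-weight prediction (pooled all-species
#' fit when the species has too few complete records); records with
#' neither get a seeded draw from the empirical mass distribution of
#' conspecifics (restricted to the same `dataset_type` partition when a
#' covariate table is supplied). Records that cannot be resolved at all
#' are excluded and counted.
#'
#' @param records validated fish-record table.
#' @param covariates optional lake-covariate table, used only to
#'   partition the empirical-draw pool by `dataset_type`.
#' @param min_fit minimum complete records for a species-specific
#'   length-weight fit (see [fit_length_weight()]).
#' @param seed integer seed for the (rare) empirical-draw branch.
#' @return the record table with `body_mass_g` complete, plus a
#'   `mass_provenance` column with levels `measured`, `length_weight`,
#'   `pooled_length_weight`, `empirical_draw`; unresolvable records are
#'   dropped and reported in `attr(, "n_unresolved")`.
#' @export
impute_missing_mass <- function(records, covariates = NULL, min_fit = 10,
                                seed = 1L) {
  records <- validate_fish_records(records)
  prov <- rep("measured", nrow(records))
  need_lw <- is.na(records$body_mass_g) & !is.na(records$total_length_cm)
  need_draw <- is.na(records$body_mass_g) & is.na(records$total_length_cm)

  if (any(need_lw)) {
    pooled <- fit_length_weight(records, NULL, min_fit = min_fit)
    for (sp in unique(records$species_id[need_lw])) {
      idx <- which(need_lw & records$species_id == sp)
      m <- fit_length_weight(records, sp, min_fit = min_fit)
      if (m$available) {
        records$body_mass_g[idx] <- predict(m, records$total_length_cm[idx])
        prov[idx] <- "length_weight"
      } else if (pooled$available) {
        records$body_mass_g[idx] <-
          predict(pooled, records$total_length_cm[idx])
        prov[idx] <- "pooled_length_weight"
      } else {
        need_draw[idx] <- TRUE  # fall through to the empirical branch
      }
    }
  }

  drop_idx <- integer(0)
  if (any(need_draw)) {
    set.seed(seed)
    partition <- rep("all", nrow(records))
    if (!is.null(covariates)) {
      partition <- covariates$dataset_type[
        match(records$lake_id, covariates$lake_id)]
      partition[is.na(partition)] <- "all"
    }
    for (idx in which(need_draw)) {
      pool <- records$body_mass_g[
        records$species_id == records$species_id[idx] &
          partition == partition[idx] & !is.na(records$body_mass_g)]
      if (!length(pool)) {  # relax the partition before giving up
        pool <- records$body_mass_g[
          records$species_id == records$species_id[idx] &
            !is.na(records$body_mass_g)]
      }
      if (length(pool)) {
        records$body_mass_g[idx] <- pool[sample.int(length(pool), 1)]
        prov[idx] <- "empirical_draw"
      } else {
        drop_idx <- c(drop_idx, idx)
      }
    }
  }

  records$mass_provenance <- prov
  if (length(drop_idx)) {
    message(length(drop_idx), " record(s) unresolvable (no mass, no length, ",
            "no conspecific masses); excluded")
    records <- records[-drop_idx, , drop = FALSE]
  }
  stopifnot(all(records$body_mass_g > 0))
  attr(records, "n_unresolved") <- length(drop_idx)
  records
}

#' Survey-inclusion filter
#'
#' A survey enters the analysis only if it sampled at least
#' `min_individuals` fish and its community contains at least one native
#' and at least one non-native species — the coexistence requirement
#' that lets invasion pressure be estimated within, rather than between,
#' communities.
#'
#' @param records imputed, validated fish-record table.
#' @param min_individuals minimum sampled individuals (default 20, which
#'   also stabilises the size-spectrum fit).
#' @return a list with `retained` (character vector of survey ids),
#'   `records` (the rows of retained surveys) and `report` (data frame
#'   `survey_id`, `reason` for every exclusion: `too_few_individuals`,
#'   `no_native_species`, `no_nonnative_species`).
#' @export
filter_surveys <- function(records, min_individuals = 20) {
  if (!nrow(records)) {
    warning("empty input: no surveys to filter")
    return(list(retained = character(0), records = records,
                report = data.frame(survey_id = character(0),
                                    reason = character(0))))
  }
  n_ind <- table(records$survey_id)
  nat <- tapply(records$origin_status == "native", records$survey_id, any)
  nn <- tapply(records$origin_status == "non_native", records$survey_id, any)
  ids <- names(n_ind)
  reasons <- list(
    too_few_individuals = ids[n_ind < min_individuals],
    no_native_species = ids[!nat[ids]],
    no_nonnative_species = ids[!nn[ids]])
  report <- do.call(rbind, lapply(names(reasons), function(r) {
    if (length(reasons[[r]])) data.frame(survey_id = reasons[[r]], reason = r)
    else NULL
  }))
  if (is.null(report)) {
    report <- data.frame(survey_id = character(0), reason = character(0))
  }
  retained <- setdiff(ids, report$survey_id)
  list(retained = retained,
       records = records[records$survey_id %in% retained, , drop = FALSE],
       report = report[order(report$survey_id), , drop = FALSE])
}
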