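#' Biomass per unit effort
#'
#' Standardises a total catch mass by gillnet effort:
#' `BPUE = (mass in kg) / (net area in km^2 x soak time in h)`, giving
#' kg km^-2 h^-1. Used for both the whole community and the native
#' community of a survey.
#'
#' @param total_mass_g total catch mass (g).
#' @param net_area_km2 total net area deployed (km^2), > 0.
#' @param duration_h soak duration (h), > 0.
#' @return BPUE in kg km^-2 h^-1.
#' @examples
#' compute_bpue(12000, 0.0005, 12)  # 2000
#' @export
compute_bpue <- function(total_mass_g, net_area_km2, duration_h) {
  if (any(net_area_km2 <= 0 | duration_h <= 0, na.rm = TRUE)) {
    stop("effort must be positive (net_area_km2 > 0, duration_h > 0)",
         call. = FALSE)
  }
  (total_mass_g / 1000) / (net_area_km2 * duration_h)
}

#' Relative non-native metrics for one survey
#'
#' The three ingredients of the invasion-pressure index: the non-native
#' share of species richness, of individual abundance, and of biomass,
#' all with whole-community denominators.
#'
#' @param records fish records of a single survey.
#' @return named numeric vector `rel_richness`, `rel_abundance`,
#'   `rel_biomass`, each in `[0, 1]`.
#' @export
relative_nn_metrics <- function(records) {
  nn <- records$origin_status == "non_native"
  c(rel_richness = length(unique(records$species_id[nn])) /
      length(unique(records$species_id)),
    rel_abundance = sum(nn) / nrow(records),
    rel_biomass = sum(records$body_mass_g[nn]) / sum(records$body_mass_g))
}

#' Non-native trophic-group dominance for one survey
#'
#' The share of all individuals (native + non-native) that are
#' non-native piscivores (`pisc_nn`) and non-native members of lower
#' trophic levels (`ltl_nn`: omnivores, detritivores, herbivores,
#' invertivores). The two shares partition the non-native individuals,
#' so `pisc_nn + ltl_nn` equals the non-native relative abundance.
#'
#' @param records fish records of a single survey; every non-native
#'   record must carry a trophic guild.
#' @return named numeric vector `pisc_nn`, `ltl_nn`.
#' @export
trophic_dominance <- function(records) {
  nn <- records$origin_status == "non_native"
  if (any(nn & is.na(records$trophic_guild))) {
    stop("non-native record(s) with missing trophic_guild", call. = FALSE)
  }
  total <- nrow(records)
  n_pisc <- sum(nn & records$trophic_guild == "piscivore")
  c(pisc_nn = n_pisc / total, ltl_nn = (sum(nn) - n_pisc) / total)
}

# first principal component of standardized columns with a sign anchor:
# the loading of `anchor` is forced positive so the axis direction is
# interpretable rather than arbitrary
first_pc_axis <- function(df, anchor) {
  keep <- vapply(df, function(col) stats::sd(col) > 0, logical(1))
  if (!all(keep)) {
    warning("dropping zero-variance column(s) before PCA: ",
            paste(names(df)[!keep], collapse = ", "))
    df <- df[, keep, drop = FALSE]
  }
  if (ncol(df) < 1) stop("no variable left for PCA", call. = FALSE)
  if (ncol(df) == 1) {
    z <- scale(df[[1]])[, 1]
    return(list(scores = z, var_explained = 1,
                loadings = stats::setNames(1, names(df))))
  }
  pca <- stats::prcomp(df, center = TRUE, scale. = TRUE)
  load1 <- pca$rotation[, 1]
  flip <- if (anchor %in% names(load1) && load1[anchor] < 0) -1 else 1
  list(scores = flip * pca$x[, 1],
       var_explained = pca$sdev[1]^2 / sum(pca$sdev^2),
       loadings = flip * load1)
}

#' Composite invasion-pressure axis
#'
#' First principal component of the standardized relative non-native
#' richness, abundance and biomass across surveys (correlation-matrix
#' PCA), sign-oriented so that more positive scores mean communities
#' more dominated by non-native species.
#'
#' @param metrics data frame with columns `rel_richness`,
#'   `rel_abundance`, `rel_biomass` (one row per survey, >= 3 surveys).
#' @return list with `scores` (per-survey `pca_inv`), `var_explained`
#'   (proportion of variance on the first axis) and `loadings`.
#' @export
invasion_pressure_axis <- function(metrics) {
  if (nrow(metrics) < 3) stop("need at least 3 surveys", call. = FALSE)
  first_pc_axis(metrics[, c("rel_richness", "rel_abundance", "rel_biomass")],
                anchor = "rel_abundance")
}

#' Precipitation intensity/seasonality axis
#'
#' First principal component of the standardized absolute monthly
#' precipitation and the relative (monthly / annual-mean) precipitation
#' across lakes, oriented so that higher scores mean wetter lakes
#' sampled in wetter seasons.
#'
#' @param covariates lake-covariate table with `precip_monthly_mm` and
#'   `precip_relative`.
#' @return list with `scores` (per-lake `precip_axis`), `var_explained`
#'   and `loadings`.
#' @export
precipitation_axis <- function(covariates) {
  if (nrow(covariates) < 3) stop("need at least 3 lakes", call. = FALSE)
  out <- first_pc_axis(
    stats::setNames(covariates[, c("precip_monthly_mm", "precip_relative")],
                    c("precip_monthly_mm", "precip_relative")),
    anchor = "precip_monthly_mm")
  names(out$scores) <- covariates$lake_id
  out
}

#' Per-survey metric table
#'
#' Assembles every survey-level predictor and response used downstream:
#' relative non-native richness/abundance/biomass, the composite
#' invasion-pressure score (`pca_inv`), trophic dominance (`pisc_nn`,
#' `ltl_nn`), whole-community and native BPUE, species richness, and the
#' per-lake precipitation axis joined back to surveys.
#'
#' @param records imputed fish records of retained surveys.
#' @param effort survey-effort table covering every retained survey.
#' @param covariates lake-covariate table covering every lake.
#' @return data frame, one row per survey: `survey_id`, `lake_id`,
#'   `sp_rich`, `rel_richness`, `rel_abundance`, `rel_biomass`,
#'   `pca_inv`, `pisc_nn`, `ltl_nn`, `bpue_all`, `bpue_native`,
#'   `precip_axis`, with attributes `pca_inv_var` and `precip_var` (the
#'   variance explained by the two first axes).
#' @export
survey_metrics <- function(records, effort, covariates) {
  by_survey <- split(records, records$survey_id)
  ids <- names(by_survey)
  base <- t(vapply(by_survey, function(d) {
    c(relative_nn_metrics(d), trophic_dominance(d),
      sp_rich = length(unique(d$species_id)),
      mass_all = sum(d$body_mass_g),
      mass_native = sum(d$body_mass_g[d$origin_status == "native"]))
  }, numeric(8)))
  out <- data.frame(survey_id = ids, base, row.names = NULL,
                    check.names = FALSE)
  eidx <- match(out$survey_id, effort$survey_id)
  if (anyNA(eidx)) {
    stop("survey_effort missing for survey(s): ",
         paste(utils::head(out$survey_id[is.na(eidx)], 5), collapse = ", "),
         call. = FALSE)
  }
  out$lake_id <- effort$lake_id[eidx]
  out$bpue_all <- compute_bpue(out$mass_all, effort$net_area_km2[eidx],
                               effort$duration_h[eidx])
  out$bpue_native <- compute_bpue(out$mass_native, effort$net_area_km2[eidx],
                                  effort$duration_h[eidx])
  out$mass_all <- out$mass_native <- NULL

  inv <- invasion_pressure_axis(out)
  out$pca_inv <- unname(inv$scores)
  pre <- precipitation_axis(covariates)
  out$precip_axis <- unname(pre$scores[match(out$lake_id,
                                             covariates$lake_id)])
  attr(out, "pca_inv_var") <- inv$var_explained
  attr(out, "precip_var") <- pre$var_explained
  attr(out, "pca_inv_loadings") <- inv$loadings
  out
}
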