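#' Logarithmic size-class grid
#'
#' Builds the 10-class (by default) grid of body-mass bins used for the
#' size-selective impact analysis. In `computed` mode the 11 edges are
#' equally spaced on the log scale between the global minimum and
#' maximum mass, `edge_j = min * (max/min)^(j/k)`; in `explicit` mode a
#' caller-supplied edge vector is validated and used verbatim (useful
#' for reproducing a published grid whose construction differs).
#'
#' @param masses all retained individual body masses (g); ignored when
#'   `explicit_edges` is given except that it may be omitted entirely.
#' @param k number of classes (default 10).
#' @param explicit_edges optional vector of `k + 1` strictly increasing
#'   edges (g).
#' @return an object of class `"size_class_grid"`: list with `edges`
#'   (length `k + 1`), `k` and `construction` (`"computed"` or
#'   `"explicit"`).
#' @export
build_size_class_grid <- function(masses = NULL, k = 10,
                                  explicit_edges = NULL) {
  if (!is.null(explicit_edges)) {
    if (is.unsorted(explicit_edges, strictly = TRUE)) {
      stop("explicit edges must be strictly increasing", call. = FALSE)
    }
    return(structure(list(edges = as.numeric(explicit_edges),
                          k = length(explicit_edges) - 1,
                          construction = "explicit"),
                     class = "size_class_grid"))
  }
  if (k < 2) stop("need k >= 2 classes", call. = FALSE)
  if (is.null(masses) || !length(masses) || any(masses <= 0)) {
    stop("need strictly positive masses to compute a grid", call. = FALSE)
  }
  lo <- min(masses)
  hi <- max(masses)
  if (lo >= hi) {
    stop("degenerate mass range: min equals max", call. = FALSE)
  }
  edges <- lo * (hi / lo)^(seq(0, k) / k)
  edges[1] <- lo
  edges[k + 1] <- hi
  structure(list(edges = edges, k = k, construction = "computed"),
            class = "size_class_grid")
}

#' @export
print.size_class_grid <- function(x, digits = 4, ...) {
  cat(sprintf("size-class grid (%s): %d classes\n", x$construction, x$k))
  lab <- format(x$edges, digits = digits, trim = TRUE)
  cat(paste0("  Class", seq_len(x$k), " [", lab[-length(lab)], ", ",
             lab[-1], ") g", collapse = "\n"), "\n")
  invisible(x)
}

# class index per mass: half-open [lower, upper) bins, final bin closed
assign_size_class <- function(masses, grid) {
  if (any(masses < grid$edges[1] | masses > grid$edges[grid$k + 1])) {
    stop("mass outside the size-class grid range", call. = FALSE)
  }
  idx <- findInterval(masses, grid$edges, rightmost.closed = TRUE)
  pmin(idx, grid$k)
}

#' Native biomass per size class, per survey
#'
#' For each survey, sums the body mass of native individuals within each
#' size class of the grid and applies the `log(x + 1)` normalisation.
#'
#' @param records fish records of retained surveys (masses imputed).
#' @param grid a [build_size_class_grid()] result covering the full
#'   native mass range.
#' @return matrix, surveys x classes, of `log(biomass_g + 1)` values;
#'   attribute `"raw"` holds the untransformed biomass matrix.
#' @export
native_biomass_by_class <- function(records, grid) {
  nat <- records[records$origin_status == "native", , drop = FALSE]
  ids <- unique(records$survey_id)
  raw <- matrix(0, length(ids), grid$k,
                dimnames = list(as.character(ids),
                                paste0("class_", seq_len(grid$k))))
  if (nrow(nat)) {
    cls <- assign_size_class(nat$body_mass_g, grid)
    agg <- rowsum(nat$body_mass_g,
                  group = paste(nat$survey_id, cls, sep = "\r"))
    key <- do.call(rbind, strsplit(rownames(agg), "\r", fixed = TRUE))
    raw[cbind(match(key[, 1], as.character(ids)), as.integer(key[, 2]))] <-
      agg[, 1]
  }
  out <- log1p(raw)
  attr(out, "raw") <- raw
  attr(out, "edges") <- grid$edges
  out
}

#' Size class vs trophic-dominance correlations
#'
#' Spearman rank correlations (midranks for ties, two-sided p-values)
#' between the log-transformed native biomass of each size class and
#' each non-native trophic-dominance predictor across surveys — the
#' screen for which native size classes are depressed where a
#' non-native trophic group dominates.
#'
#' @param class_matrix a [native_biomass_by_class()] matrix.
#' @param metrics survey-metric table with `pisc_nn` and `ltl_nn`;
#'   matched to the matrix rows by `survey_id`.
#' @return data frame with one row per class x predictor: `class`,
#'   `class_range_g`, `predictor`, `rho`, `p_value`, `n`, `flag`
#'   (`"ok"`, or `"zero_variance"` where the correlation is undefined
#'   and reported as NA).
#' @export
class_dominance_correlations <- function(class_matrix, metrics) {
  if (nrow(class_matrix) < 4) stop("need at least 4 surveys", call. = FALSE)
  idx <- match(rownames(class_matrix), as.character(metrics$survey_id))
  if (anyNA(idx)) stop("metrics missing for some surveys", call. = FALSE)
  edges <- attr(class_matrix, "edges")
  rows <- list()
  for (pred in c("pisc_nn", "ltl_nn")) {
    pv <- metrics[[pred]][idx]
    for (j in seq_len(ncol(class_matrix))) {
      y <- class_matrix[, j]
      rng <- if (is.null(edges)) NA_character_ else {
        sprintf("[%.4g, %.4g]", edges[j], edges[j + 1])
      }
      if (stats::sd(y) == 0 || stats::sd(pv) == 0) {
        rows[[length(rows) + 1]] <- data.frame(
          class = j, class_range_g = rng, predictor = pred,
          rho = NA_real_, p_value = NA_real_, n = length(y),
          flag = "zero_variance")
      } else {
        ct <- suppressWarnings(
          stats::cor.test(pv, y, method = "spearman", exact = FALSE))
        rows[[length(rows) + 1]] <- data.frame(
          class = j, class_range_g = rng, predictor = pred,
          rho = unname(ct$estimate), p_value = ct$p.value, n = length(y),
          flag = "ok")
      }
    }
  }
  do.call(rbind, rows)
}
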