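#' The bounded power-law (PLB) distribution
#'
#' Density, distribution function, quantile function and random generation
#' for the bounded power law with exponent `lambda` on `[xmin, xmax]`,
#' the distribution underlying the individual size spectrum of a fish
#' community: frequency declines (for negative `lambda`) as a power of
#' body mass.
#'
#' For `lambda != -1` the density is
#' `f(x) = (lambda + 1) * x^lambda / (xmax^(lambda+1) - xmin^(lambda+1))`,
#' and for `lambda = -1` it is `f(x) = x^-1 / log(xmax / xmin)`, in both
#' cases restricted to `xmin <= x <= xmax`.
#'
#' @param x,q vector of masses (g).
#' @param p vector of probabilities.
#' @param n number of draws.
#' @param lambda exponent of the bounded power law (dimensionless).
#'   Negative values give declining size spectra; `lambda = -1` is the
#'   log-uniform special case, handled exactly.
#' @param xmin,xmax lower and upper bounds of the support (g),
#'   `0 < xmin < xmax`.
#' @param log,log.p logical; if `TRUE`, probabilities/densities are given
#'   on the log scale.
#' @return `dplb` gives the density, `pplb` the CDF, `qplb` the quantile
#'   function and `rplb` random draws.
#' @seealso [fit_plb()] for maximum-likelihood estimation of `lambda`.
#' @examples
#' x <- rplb(500, lambda = -2, xmin = 0.5, xmax = 1000)
#' range(x)
#' qplb(0.5, lambda = -2, xmin = 1, xmax = 10)  # 1/0.55
#' @export
dplb <- function(x, lambda = -2, xmin = 1, xmax = 100, log = FALSE) {
  check_plb_params(lambda, xmin, xmax)
  lp <- rep(-Inf, length(x))
  ok <- x >= xmin & x <= xmax
  if (is_log_uniform(lambda)) {
    lp[ok] <- -log(x[ok]) - log(log(xmax / xmin))
  } else {
    lp[ok] <- log((lambda + 1) / (xmax^(lambda + 1) - xmin^(lambda + 1))) +
      lambda * log(x[ok])
  }
  if (log) lp else exp(lp)
}

#' @rdname dplb
#' @export
pplb <- function(q, lambda = -2, xmin = 1, xmax = 100, log.p = FALSE) {
  check_plb_params(lambda, xmin, xmax)
  q <- pmin(pmax(q, xmin), xmax)
  if (is_log_uniform(lambda)) {
    p <- (log(q) - log(xmin)) / (log(xmax) - log(xmin))
  } else {
    l1 <- lambda + 1
    p <- (q^l1 - xmin^l1) / (xmax^l1 - xmin^l1)
  }
  p <- pmin(pmax(p, 0), 1)
  if (log.p) log(p) else p
}

#' @rdname dplb
#' @export
qplb <- function(p, lambda = -2, xmin = 1, xmax = 100) {
  check_plb_params(lambda, xmin, xmax)
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("'p' must lie in [0, 1]", call. = FALSE)
  }
  if (is_log_uniform(lambda)) {
    x <- xmin * (xmax / xmin)^p
  } else {
    l1 <- lambda + 1
    x <- (xmin^l1 + p * (xmax^l1 - xmin^l1))^(1 / l1)
  }
  # guard endpoints against round-off
  x[p == 0] <- xmin
  x[p == 1] <- xmax
  pmin(pmax(x, xmin), xmax)
}

#' @rdname dplb
#' @export
rplb <- function(n, lambda = -2, xmin = 1, xmax = 100) {
  qplb(stats::runif(n), lambda = lambda, xmin = xmin, xmax = xmax)
}

# the lambda = -1 branch is a removable singularity; evaluate it whenever
# |lambda + 1| is below this to avoid catastrophic cancellation
.plb_singular_tol <- 1e-8

is_log_uniform <- function(lambda) abs(lambda + 1) < .plb_singular_tol

check_plb_params <- function(lambda, xmin, xmax) {
  if (!is.finite(lambda)) stop("'lambda' must be finite", call. = FALSE)
  if (!(is.finite(xmin) && is.finite(xmax) && xmin > 0 && xmax > xmin)) {
    stop("need 0 < xmin < xmax", call. = FALSE)
  }
  invisible(TRUE)
}

#' Negative log-likelihood of the bounded power law
#'
#' Evaluates the PLB negative log-likelihood for a sample of body masses.
#' For `lambda != -1` this is
#' `-n * log((lambda+1) / (xmax^(lambda+1) - xmin^(lambda+1))) - lambda * sum(log(x))`
#' (the ratio is positive for every `lambda` because numerator and
#' denominator share sign), and at `lambda = -1` it is
#' `n * log(log(xmax) - log(xmin)) + sum(log(x))`. The two branches join
#' continuously; the `lambda = -1` form is used whenever
#' `|lambda + 1| < 1e-8`.
#'
#' @param lambda exponent value(s) at which to evaluate; vectorised.
#' @param x body masses (g), all within `[xmin, xmax]`. May be omitted if
#'   `n` and `sumlogx` are supplied directly (sufficient statistics).
#' @param xmin,xmax support bounds (g).
#' @param n sample size; defaults to `length(x)`.
#' @param sumlogx sum of `log(x)`; defaults to `sum(log(x))`.
#' @return numeric vector of negative log-likelihood values, finite for
#'   all finite `lambda`.
#' @examples
#' plb_negloglik(-2, c(1, 10), xmin = 1, xmax = 10)  # 4.39445
#' plb_negloglik(-1, c(1, 10), xmin = 1, xmax = 10)  # 3.97065
#' @export
plb_negloglik <- function(lambda, x = NULL, xmin, xmax,
                          n = length(x), sumlogx = sum(log(x))) {
  if (!(is.finite(xmin) && is.finite(xmax) && xmin > 0 && xmax > xmin)) {
    stop("need 0 < xmin < xmax", call. = FALSE)
  }
  if (!is.null(x)) {
    if (any(x < xmin | x > xmax)) {
      stop("all masses must lie within [xmin, xmax]", call. = FALSE)
    }
  }
  if (n < 1) stop("need at least one observation", call. = FALSE)
  vapply(lambda, function(l) {
    if (!is.finite(l)) return(Inf)
    if (is_log_uniform(l)) {
      n * log(log(xmax) - log(xmin)) + sumlogx
    } else {
      l1 <- l + 1
      -n * log(l1 / (xmax^l1 - xmin^l1)) - l * sumlogx
    }
  }, numeric(1))
}

#' Fit a bounded power law to individual body masses
#'
#' Maximum-likelihood estimation of the size-spectrum exponent `lambda`
#' for one community sample: the estimate minimises [plb_negloglik()] over
#' a bounded search interval, and a profile-likelihood confidence interval
#' is attached. Less negative ("flatter") exponents indicate relatively
#' more large-bodied individuals.
#'
#' The optimisation is one-dimensional bounded minimisation over
#' `lambda_range`, run both over the full range and restarted on a
#' narrower bracket around -1.5 (a typical fish community value); the
#' better of the two optima is kept. The negative log-likelihood is
#' evaluated through its sufficient statistics, so each evaluation is
#' O(1) after one pass over the data.
#'
#' @param x body masses (g), strictly positive.
#' @param xmin,xmax support bounds (g). Default to the observed minimum
#'   and maximum of `x` (the community's own size range).
#' @param min_n minimum sample size; smaller samples are refused. The
#'   default 20 matches the survey-inclusion filter of
#'   [filter_surveys()].
#' @param level confidence level of the profile-likelihood interval.
#' @param lambda_range search interval for the exponent. The default
#'   `c(-10, 5)` accommodates both steep spectra and the positive
#'   exponents occasionally seen in native-only communities.
#' @return an object of class `"plb_fit"`: a list with components
#'   `lambda` (the MLE), `ci` (profile interval), `se` (curvature-based
#'   standard error), `n`, `xmin`, `xmax`, `nll_min`, `converged`,
#'   `level` and `data` (the masses, for methods).
#' @seealso [confint.plb_fit()], [simulate.plb_fit()], [plot.plb_fit()],
#'   [cutoff_sensitivity()].
#' @examples
#' set.seed(1)
#' fit <- fit_plb(rplb(1000, lambda = -1.8, xmin = 0.5, xmax = 2000))
#' coef(fit)
#' confint(fit)
#' @export
fit_plb <- function(x, xmin = NULL, xmax = NULL, min_n = 20, level = 0.95,
                    lambda_range = c(-10, 5)) {
  x <- as.numeric(x)
  if (anyNA(x)) stop("masses must not contain NA", call. = FALSE)
  n <- length(x)
  if (n < min_n) {
    stop(sprintf("insufficient sample: n = %d < min_n = %d", n, min_n),
         call. = FALSE)
  }
  if (any(x <= 0)) stop("masses must be strictly positive", call. = FALSE)
  if (is.null(xmin)) xmin <- min(x)
  if (is.null(xmax)) xmax <- max(x)
  if (xmin >= xmax) {
    stop("degenerate spectrum: xmin >= xmax (all masses identical?)",
         call. = FALSE)
  }
  if (any(x < xmin | x > xmax)) {
    stop("all masses must lie within [xmin, xmax]", call. = FALSE)
  }
  sumlogx <- sum(log(x))
  nll <- function(l) plb_negloglik(l, xmin = xmin, xmax = xmax,
                                   n = n, sumlogx = sumlogx)
  opt <- stats::optimize(nll, interval = lambda_range, tol = 1e-10)
  # restart on a bracket around the typical fish-community exponent
  restart <- c(max(lambda_range[1], -4), min(lambda_range[2], 1))
  opt2 <- stats::optimize(nll, interval = restart, tol = 1e-10)
  if (opt2$objective < opt$objective) opt <- opt2
  lambda_hat <- opt$minimum
  nll_min <- opt$objective
  converged <- is.finite(nll_min) &&
    lambda_hat > lambda_range[1] + 1e-6 && lambda_hat < lambda_range[2] - 1e-6
  # curvature-based SE (central second difference of the NLL)
  h <- 1e-4
  d2 <- (nll(lambda_hat + h) - 2 * nll_min + nll(lambda_hat - h)) / h^2
  se <- if (is.finite(d2) && d2 > 0) 1 / sqrt(d2) else NA_real_
  fit <- structure(
    list(lambda = lambda_hat, ci = c(NA_real_, NA_real_), se = se,
         n = n, xmin = xmin, xmax = xmax, nll_min = nll_min,
         converged = converged, level = level,
         lambda_range = lambda_range, sumlogx = sumlogx, data = x),
    class = "plb_fit")
  fit$ci <- tryCatch(profile_ci(fit, level), error = function(e) {
    c(NA_real_, NA_real_)
  })
  fit
}

# profile-likelihood interval: lambda values where the NLL rises by
# qchisq(level, 1) / 2 (1.92 at 95%) above its minimum
profile_ci <- function(fit, level = fit$level) {
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  target <- fit$nll_min + stats::qchisq(level, df = 1) / 2
  nll <- function(l) plb_negloglik(l, xmin = fit$xmin, xmax = fit$xmax,
                                   n = fit$n, sumlogx = fit$sumlogx)
  g <- function(l) nll(l) - target
  step <- if (is.finite(fit$se)) 2 * fit$se else 0.5
  lo_bound <- fit$lambda - step
  while (g(lo_bound) < 0 && lo_bound > fit$lambda - 50) {
    lo_bound <- lo_bound - step
  }
  hi_bound <- fit$lambda + step
  while (g(hi_bound) < 0 && hi_bound < fit$lambda + 50) {
    hi_bound <- hi_bound + step
  }
  lo <- stats::uniroot(g, c(lo_bound, fit$lambda), tol = 1e-9)$root
  hi <- stats::uniroot(g, c(fit$lambda, hi_bound), tol = 1e-9)$root
  c(lo, hi)
}

#' @export
print.plb_fit <- function(x, digits = 4, ...) {
  cat("Bounded power-law (PLB) size-spectrum fit\n")
  cat(sprintf("  lambda = %s  [%s, %s] (%d%% profile CI)\n",
              format(x$lambda, digits = digits),
              format(x$ci[1], digits = digits),
              format(x$ci[2], digits = digits),
              round(100 * x$level)))
  cat(sprintf("  n = %d individuals, mass range [%.3g, %.3g] g\n",
              x$n, x$xmin, x$xmax))
  if (!x$converged) cat("  WARNING: optimiser did not converge\n")
  invisible(x)
}

#' @export
coef.plb_fit <- function(object, ...) c(lambda = object$lambda)

#' @export
logLik.plb_fit <- function(object, ...) {
  structure(-object$nll_min, df = 1, nobs = object$n, class = "logLik")
}

#' Profile-likelihood confidence interval for a PLB fit
#'
#' @param object a [fit_plb()] result.
#' @param parm ignored (the model has a single parameter).
#' @param level confidence level.
#' @param ... unused.
#' @return a 1 x 2 matrix of interval bounds for `lambda`.
#' @export
confint.plb_fit <- function(object, parm = "lambda", level = 0.95, ...) {
  ci <- if (isTRUE(all.equal(level, object$level))) {
    object$ci
  } else {
    profile_ci(object, level)
  }
  matrix(ci, nrow = 1,
         dimnames = list("lambda",
                         sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                                    1 - (1 - level) / 2))))
}

#' @export
summary.plb_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.plb_fit")
}

#' @export
print.summary.plb_fit <- function(x, digits = 4, ...) {
  f <- x$fit
  print(f, digits = digits)
  cat(sprintf("  SE(lambda) = %s,  min NLL = %s\n",
              format(f$se, digits = digits),
              format(f$nll_min, digits = digits)))
  invisible(x)
}

#' Simulate body masses from a fitted bounded power law
#'
#' @param object a [fit_plb()] result.
#' @param nsim number of replicate samples.
#' @param seed optional integer seed, applied via [set.seed()].
#' @param n sample size per replicate; defaults to the fitted sample size.
#' @param ... unused.
#' @return a data frame with `nsim` columns of simulated masses (g).
#' @export
simulate.plb_fit <- function(object, nsim = 1, seed = NULL,
                             n = object$n, ...) {
  if (!is.null(seed)) set.seed(seed)
  out <- as.data.frame(replicate(nsim, rplb(n, lambda = object$lambda,
                                            xmin = object$xmin,
                                            xmax = object$xmax),
                                 simplify = FALSE))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Rank-frequency plot of a PLB fit
#'
#' Plots the observed masses against the number of individuals of that
#' mass or larger (both on log axes) with the fitted PLB expectation
#' overlaid — the standard visual check of a size-spectrum fit.
#'
#' @param x a [fit_plb()] result.
#' @param ... passed to [graphics::plot()].
#' @export
plot.plb_fit <- function(x, ...) {
  xs <- sort(x$data, decreasing = TRUE)
  rank <- seq_along(xs)
  graphics::plot(xs, rank, log = "xy", xlab = "body mass (g)",
                 ylab = "number of individuals >= mass", ...)
  grid_x <- exp(seq(log(x$xmin), log(x$xmax), length.out = 200))
  expected <- x$n * (1 - pplb(grid_x, x$lambda, x$xmin, x$xmax))
  graphics::lines(grid_x, pmax(expected, 1e-8), col = "red", lwd = 2)
  invisible(x)
}

#' Residuals of a PLB fit
#'
#' Quantile residuals: the fitted CDF evaluated at the ordered data is
#' compared with uniform plotting positions, so systematic departures
#' flag lack of fit of the bounded power law.
#'
#' @param object a [fit_plb()] result.
#' @param ... unused.
#' @return numeric vector `pplb(sorted masses) - (i - 0.5)/n`.
#' @export
residuals.plb_fit <- function(object, ...) {
  xs <- sort(object$data)
  pplb(xs, object$lambda, object$xmin, object$xmax) -
    (seq_along(xs) - 0.5) / length(xs)
}

#' Fit size spectra for every survey in a fish-record table
#'
#' Convenience wrapper that fits [fit_plb()] per survey, for the whole
#' community and (optionally) the native species only, in one pass.
#'
#' @param records a validated fish-record table (see [read_fish_records()]).
#' @param min_n minimum individuals per fit (default 20).
#' @param native_only logical; also fit native-only spectra?
#' @return a data frame with one row per survey: `survey_id`, `n`,
#'   `xmin_g`, `xmax_g`, `lambda_hat`, `ci_low`, `ci_high`, `nll_min`,
#'   `converged`, and when `native_only = TRUE` the same columns with a
#'   `_native` suffix (NA where too few native individuals remain).
#' @export
fit_spectra <- function(records, min_n = 20, native_only = TRUE) {
  stopifnot(is.data.frame(records))
  ids <- unique(records$survey_id)
  one <- function(m) {
    if (length(m) < min_n || length(unique(m)) < 2) {
      return(c(n = length(m), xmin_g = NA, xmax_g = NA, lambda_hat = NA,
               ci_low = NA, ci_high = NA, nll_min = NA, converged = 0))
    }
    f <- fit_plb(m, min_n = min_n)
    c(n = f$n, xmin_g = f$xmin, xmax_g = f$xmax, lambda_hat = f$lambda,
      ci_low = f$ci[1], ci_high = f$ci[2], nll_min = f$nll_min,
      converged = as.numeric(f$converged))
  }
  by_survey <- split(records, records$survey_id)[as.character(ids)]
  all_fit <- t(vapply(by_survey, function(d) one(d$body_mass_g),
                      numeric(8)))
  out <- data.frame(survey_id = ids, all_fit, row.names = NULL)
  if (native_only) {
    nat_fit <- t(vapply(by_survey, function(d) {
      one(d$body_mass_g[d$origin_status == "native"])
    }, numeric(8)))
    colnames(nat_fit) <- paste0(colnames(nat_fit), "_native")
    out <- cbind(out, as.data.frame(nat_fit, row.names = NULL))
  }
  out
}

#' Sensitivity of size-spectrum exponents to a minimum-mass cutoff
#'
#' Refits the per-survey exponent with the lower bound fixed at each
#' cutoff (individuals below the cutoff removed), then reports the
#' Spearman rank-correlation concordance between the exponent vectors
#' across cutoffs, over the surveys that remain fittable at every cutoff.
#'
#' @param records fish-record table.
#' @param cutoffs ascending minimum body masses (g). The default
#'   `c(0.5, 1, 2, 3, 4)` spans the range used for multimesh-gillnet
#'   surveys, 4 g being the threshold recommended for the European CEN
#'   protocol.
#' @param min_n minimum individuals per refit.
#' @return a list with `exponents` (survey x cutoff matrix, NA where a
#'   survey falls below `min_n` after truncation), `concordance`
#'   (cutoff x cutoff Spearman matrix over complete surveys), `n_common`
#'   (number of surveys present at every cutoff) and `dropped`
#'   (per-cutoff count of unfittable surveys).
#' @export
cutoff_sensitivity <- function(records, cutoffs = c(0.5, 1, 2, 3, 4),
                               min_n = 20) {
  if (is.unsorted(cutoffs, strictly = TRUE)) {
    stop("'cutoffs' must be strictly ascending", call. = FALSE)
  }
  ids <- unique(records$survey_id)
  by_survey <- split(records$body_mass_g, records$survey_id)[as.character(ids)]
  expo <- matrix(NA_real_, length(ids), length(cutoffs),
                 dimnames = list(as.character(ids),
                                 paste0("cutoff_", cutoffs)))
  for (j in seq_along(cutoffs)) {
    cut <- cutoffs[j]
    for (i in seq_along(ids)) {
      m <- by_survey[[i]]
      m <- m[m >= cut]
      if (length(m) >= min_n && length(unique(m)) >= 2) {
        expo[i, j] <- fit_plb(m, xmin = cut, min_n = min_n)$lambda
      }
    }
  }
  complete <- stats::complete.cases(expo)
  n_common <- sum(complete)
  k <- length(cutoffs)
  conc <- matrix(NA_real_, k, k, dimnames = dimnames(expo)[c(2, 2)])
  if (n_common >= 3) {
    conc <- stats::cor(expo[complete, , drop = FALSE], method = "spearman")
  } else {
    warning("fewer than 3 surveys present at every cutoff; ",
            "concordance undefined")
  }
  list(exponents = expo, concordance = conc, n_common = n_common,
       dropped = colSums(is.na(expo)))
}
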