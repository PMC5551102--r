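#' 95th percentile of stem diameters
#'
#' The species' "maximum" stem diameter is taken as the 95th percentile of
#' the measured diameters rather than the observed maximum, which makes the
#' standardization robust to single outlying stems. Linear interpolation of
#' order statistics is used, with index h = (n - 1) p + 1 on the sorted
#' sample (the default quantile definition of most statistical software).
#'
#' @param diameters Numeric vector of positive stem diameters (cm), length
#'   at least 2.
#' @return The 95th percentile, a positive scalar.
#' @export
#' @examples
#' percentile95(1:21)      # exactly the 20th order statistic
#' percentile95(c(0.5, 1.5))
percentile95 <- function(diameters) {
  diameters <- as.numeric(diameters)
  if (length(diameters) < 2L)
    stop("need at least 2 diameters to estimate the 95th percentile",
         call. = FALSE)
  if (any(!is.finite(diameters) | diameters <= 0))
    stop("diameters must be positive and finite", call. = FALSE)
  unname(stats::quantile(diameters, probs = 0.95, type = 7))
}

#' Relative plant sizes
#'
#' Standardizes stem diameters by the species' estimated maximum diameter
#' (its 95th percentile), giving the relative plant size S. About 5% of a
#' sample standardized by its own 95th percentile exceeds 1.
#'
#' @param diameters Numeric vector of stem diameters (cm).
#' @param dbh95 Positive scalar, the species' 95th-percentile diameter (cm).
#' @return Numeric vector \code{diameters / dbh95}.
#' @export
relative_sizes <- function(diameters, dbh95) {
  if (!is.numeric(dbh95) || length(dbh95) != 1L || !is.finite(dbh95) ||
      dbh95 <= 0)
    stop("dbh95 must be a single positive number", call. = FALSE)
  as.numeric(diameters) / dbh95
}

#' Fit the logistic flowering-probability model
#'
#' Fits P = exp(a + b ln S) / (1 + exp(a + b ln S)), the probability that an
#' individual of relative size S bears flowers, by maximum likelihood
#' (iteratively reweighted least squares, convergence when the relative
#' change in deviance falls below 1e-10, at most 100 iterations).
#'
#' Quasi-complete separation (all small plants sterile, all large plants
#' flowering, with no overlap) sends the ML coefficients to infinity; the
#' fit is flagged via \code{separation_flag} when any coefficient exceeds
#' 50 in absolute value at termination.
#'
#' @param sizes Positive numeric vector of relative plant sizes.
#' @param flowered Logical vector (or 0/1) of the same length.
#' @return An object of class \code{"logistic_fit"}: a list with elements
#'   \code{a} (intercept), \code{b} (slope on ln S), \code{loglik},
#'   \code{n}, \code{converged} and \code{separation_flag}.
#' @export
#' @examples
#' s <- c(0.1, 0.15, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 1.0)
#' y <- c(0, 0, 0, 1, 0, 1, 1, 1, 1, 1)
#' fit_flowering_logistic(s, y)
fit_flowering_logistic <- function(sizes, flowered) {
  sizes <- as.numeric(sizes)
  flowered <- as.logical(flowered)
  if (length(sizes) != length(flowered))
    stop("sizes and flowered must have equal length", call. = FALSE)
  if (length(sizes) < 2L)
    stop("need at least 2 observations", call. = FALSE)
  if (any(!is.finite(sizes) | sizes <= 0))
    stop("relative sizes must be positive", call. = FALSE)
  if (anyNA(flowered))
    stop("flowered must not contain missing values", call. = FALSE)
  if (all(flowered) || !any(flowered))
    stop("degenerate response: need at least one flowering and one ",
         "non-flowering record", call. = FALSE)
  x <- log(sizes)
  fit <- suppressWarnings(
    stats::glm(flowered ~ x, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 100L))
  )
  cf <- unname(stats::coef(fit))
  structure(list(
    a = cf[1L],
    b = cf[2L],
    loglik = as.numeric(stats::logLik(fit)),
    n = length(sizes),
    converged = fit$converged,
    separation_flag = any(abs(cf) > 50)
  ), class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic flowering model (n = %d): a = %.4f, b = %.4f, lnL = %.3f\n",
              x$n, x$a, x$b, x$loglik))
  if (x$separation_flag) cat("  [quasi-complete separation detected]\n")
  invisible(x)
}

#' Relative size at 50% flowering probability
#'
#' Inverts the fitted logistic model at P = 0.5: the relative plant size at
#' which half of the individuals bear flowers is S0.5 = exp(-a/b). It is
#' defined only when flowering probability increases with size (b > 0).
#'
#' @param fit A \code{"logistic_fit"} object, or a list with elements
#'   \code{a} and \code{b}.
#' @return The threshold size S0.5, a positive scalar.
#' @export
#' @examples
#' s50(list(a = 7.378, b = 4.812))  # 0.216
s50 <- function(fit) {
  if (!is.finite(fit$b) || fit$b <= 0)
    stop("S0.5 is undefined: flowering probability is non-increasing ",
         "in size (b <= 0)", call. = FALSE)
  exp(-fit$a / fit$b)
}

#' Maturity estimate for one species
#'
#' Composes the full per-species workflow: take the species' records from an
#' observation table, standardize diameters by their 95th percentile, fit
#' the logistic flowering model, and return the relative threshold size.
#'
#' @param observations An observation data frame ([read_observations()]).
#' @param species_id The species to estimate.
#' @param min_n Minimum number of records required (default 20, the survey's
#'   sampling floor); set lower to relax.
#' @return A list of class \code{"maturity_estimate"} with elements
#'   \code{species}, \code{s50}, \code{dbh95_cm}, \code{n} and \code{fit}.
#' @export
species_maturity <- function(observations, species_id, min_n = 20L) {
  rows <- observations[observations$species == species_id, , drop = FALSE]
  if (nrow(rows) == 0L)
    stop("species not found in observation table: ", species_id,
         call. = FALSE)
  if (nrow(rows) < min_n)
    stop("insufficient data for ", species_id, ": ", nrow(rows),
         " record(s), need at least ", min_n, call. = FALSE)
  dbh95 <- percentile95(rows$diameter_cm)
  fit <- fit_flowering_logistic(relative_sizes(rows$diameter_cm, dbh95),
                                rows$flowered)
  structure(list(species = species_id, s50 = s50(fit), dbh95_cm = dbh95,
                 n = nrow(rows), fit = fit),
            class = "maturity_estimate")
}

#' @export
print.maturity_estimate <- function(x, ...) {
  cat(sprintf("%s: S0.5 = %.3f (dbh95 = %.1f cm, n = %d)\n",
              x$species, x$s50, x$dbh95_cm, x$n))
  invisible(x)
}

#' Estimate maturity thresholds for every species in a table
#'
#' @param observations An observation data frame.
#' @param min_n Minimum records per species (default 20).
#' @param on_error \code{"stop"} (default) to propagate per-species fitting
#'   errors, or \code{"omit"} to drop such species with a warning (e.g. a
#'   species in which every surveyed individual flowered carries no
#'   information about its threshold).
#' @return A data frame with one row per species: \code{species},
#'   \code{s50}, \code{dbh95_cm}, \code{n_obs}, \code{converged},
#'   \code{separation_flag}.
#' @export
all_species_maturity <- function(observations, min_n = 20L,
                                 on_error = c("stop", "omit")) {
  on_error <- match.arg(on_error)
  sp <- unique(observations$species)
  est <- lapply(sp, function(s) {
    if (on_error == "stop") species_maturity(observations, s, min_n)
    else tryCatch(species_maturity(observations, s, min_n),
                  error = function(e) {
                    warning("omitting ", s, ": ", conditionMessage(e),
                            call. = FALSE)
                    NULL
                  })
  })
  keep <- !vapply(est, is.null, NA)
  sp <- sp[keep]; est <- est[keep]
  data.frame(
    species = sp,
    s50 = vapply(est, function(e) e$s50, 0),
    dbh95_cm = vapply(est, function(e) e$dbh95_cm, 0),
    n_obs = vapply(est, function(e) e$n, 0L),
    converged = vapply(est, function(e) e$fit$converged, NA),
    separation_flag = vapply(est, function(e) e$fit$separation_flag, NA),
    stringsAsFactors = FALSE
  )
}
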