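# Align a (possibly named) trait vector with the tip order of C.
align_trait <- function(x, C) {
  if (!is.null(names(x)) && !is.null(rownames(C))) {
    miss <- setdiff(rownames(C), names(x))
    if (length(miss) > 0L)
      stop("trait values missing for tip(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    x <- x[rownames(C)]
  }
  if (length(x) != nrow(C))
    stop("trait vector length (", length(x), ") does not match the ",
         "covariance dimension (", nrow(C), ")", call. = FALSE)
  if (anyNA(x)) stop("trait vector contains missing values", call. = FALSE)
  as.numeric(x)
}

# Cholesky solve of C z = b; fails loudly on a singular matrix.
chol_solve <- function(C, b) {
  R <- tryCatch(chol(C), error = function(e)
    stop("phylogenetic covariance matrix is singular or not positive ",
         "definite", call. = FALSE))
  backsolve(R, backsolve(R, b, transpose = TRUE))
}

#' Phylogenetically weighted mean (GLS root-state estimate)
#'
#' The generalized-least-squares estimate of the ancestral (root) state:
#' \eqn{\hat a = (1' C^{-1} 1)^{-1} 1' C^{-1} x}. With \code{C} the
#' identity this is the arithmetic mean.
#'
#' @param x Trait vector (named by tip, or in the tip order of \code{C}).
#' @param C Phylogenetic covariance matrix ([phylo_covariance()]).
#' @return The weighted mean, a scalar.
#' @export
phylo_mean <- function(x, C) {
  x <- align_trait(x, C)
  ones <- rep(1, length(x))
  z <- chol_solve(C, cbind(x, ones))
  sum(z[, 1L]) / sum(z[, 2L])
}

#' Blomberg's K statistic
#'
#' The ratio of the observed mean squared error of the trait about the
#' phylogenetic mean (computed as if tips were independent) to the mean
#' squared error under the phylogenetic covariance, scaled by the same
#' ratio expected under Brownian motion on the given tree. K = 1 matches
#' the Brownian expectation; K < 1 indicates less resemblance among
#' relatives than Brownian motion predicts.
#'
#' @inheritParams phylo_mean
#' @return The K statistic, a positive scalar.
#' @export
blomberg_k <- function(x, C) {
  x <- align_trait(x, C)
  n <- length(x)
  if (n < 3L) stop("need at least 3 tips", call. = FALSE)
  if (stats::var(x) == 0)
    stop("trait is constant across tips; K is undefined", call. = FALSE)
  ones <- rep(1, n)
  z <- chol_solve(C, cbind(x, ones))
  a_hat <- sum(z[, 1L]) / sum(z[, 2L])
  r <- x - a_hat
  mse0 <- sum(r * r) / (n - 1)
  mse <- drop(crossprod(r, chol_solve(C, r))) / (n - 1)
  expected <- (sum(diag(C)) - n / sum(z[, 2L])) / (n - 1)
  (mse0 / mse) / expected
}

#' Permutation test for Blomberg's K
#'
#' Permutes trait values across tips \code{n_perm} times and compares the
#' observed phylogenetic mean squared error with its permutation
#' distribution (smaller MSE = stronger signal). The observed arrangement
#' is included in the null set, so with 999 permutations p is a multiple
#' of 1/1000.
#'
#' @inheritParams phylo_mean
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed (default 1); results are reproducible
#'   bit-for-bit given \code{(seed, n_perm)}.
#' @return A list of class \code{"signal_test"} with elements
#'   \code{statistic_name} ("K"), \code{estimate}, \code{p_value} and
#'   \code{n_permutations}.
#' @export
blomberg_k_test <- function(x, C, n_perm = 999L, seed = 1L) {
  x <- align_trait(x, C)
  k_obs <- blomberg_k(x, C)
  n <- length(x)
  ones <- rep(1, n)
  Ci <- chol_solve(C, diag(n))  # reused across permutations
  mse_of <- function(v) {
    a_hat <- sum(Ci %*% v) / sum(Ci %*% ones)
    r <- v - a_hat
    drop(crossprod(r, Ci %*% r)) / (n - 1)
  }
  mse_obs <- mse_of(x)
  perm_mse <- with_local_seed(seed, {
    vapply(seq_len(n_perm), function(i) mse_of(sample(x)), 0)
  })
  p <- (1 + sum(perm_mse <= mse_obs)) / (1 + n_perm)
  structure(list(statistic_name = "K", estimate = k_obs, p_value = p,
                 n_permutations = as.integer(n_perm)),
            class = "signal_test")
}

# Profile log-likelihood of the lambda model at a given lambda:
# x ~ N(a 1, sigma2 C_lambda), with a and sigma2 profiled out analytically.
lambda_loglik <- function(x, C, lambda) {
  n <- length(x)
  Cl <- lambda_transform(C, lambda)
  R <- chol(Cl)
  logdet <- 2 * sum(log(diag(R)))
  z <- backsolve(R, backsolve(R, cbind(x, rep(1, n)), transpose = TRUE))
  a_hat <- sum(z[, 1L]) / sum(z[, 2L])
  r <- x - a_hat
  s2 <- drop(crossprod(r, backsolve(R, backsolve(R, r, transpose = TRUE)))) / n
  -0.5 * (n * log(2 * pi * s2) + logdet + n)
}

#' Pagel's lambda by maximum likelihood, with a likelihood-ratio test
#'
#' Maximizes the profile log-likelihood of the lambda model over
#' \eqn{\lambda \in [0, 1]} by bounded scalar optimization (the root state
#' and rate are profiled out analytically at each lambda), and tests
#' lambda = 0 (no phylogenetic signal) with a likelihood-ratio statistic
#' against a chi-squared distribution with one degree of freedom.
#'
#' @inheritParams phylo_mean
#' @param tol Convergence tolerance of the scalar optimizer (default 1e-8).
#' @return A list of class \code{"signal_test"} with elements
#'   \code{statistic_name} ("lambda"), \code{estimate}, \code{p_value},
#'   \code{loglik_at_estimate} and \code{loglik_at_null}.
#' @export
pagel_lambda_ml <- function(x, C, tol = 1e-8) {
  x <- align_trait(x, C)
  if (length(x) < 3L) stop("need at least 3 tips", call. = FALSE)
  d <- diag(C)
  if (diff(range(d)) > 1e-6 * max(d))
    warning("covariance diagonal is not constant (non-ultrametric tree); ",
            "the lambda model assumes an ultrametric tree")
  f <- function(l) lambda_loglik(x, C, l)
  opt <- stats::optimize(f, interval = c(0, 1), maximum = TRUE, tol = tol)
  # the interior optimizer cannot land exactly on a boundary; check both
  cand_l <- c(opt$maximum, 0, 1)
  cand_ll <- c(opt$objective, f(0), f(1))
  best <- which.max(cand_ll)
  l_hat <- cand_l[best]
  ll_hat <- cand_ll[best]
  ll0 <- cand_ll[2L]
  lr <- max(0, 2 * (ll_hat - ll0))
  p <- stats::pchisq(lr, df = 1, lower.tail = FALSE)
  structure(list(statistic_name = "lambda", estimate = l_hat, p_value = p,
                 loglik_at_estimate = ll_hat, loglik_at_null = ll0),
            class = "signal_test")
}

#' @export
print.signal_test <- function(x, ...) {
  if (x$statistic_name == "K")
    cat(sprintf("Blomberg's K = %.3f, P = %.3f (%d permutations)\n",
                x$estimate, x$p_value, x$n_permutations))
  else
    cat(sprintf("Pagel's lambda = %.3f, P = %.3f (LRT vs lambda = 0)\n",
                x$estimate, x$p_value))
  invisible(x)
}
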