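.predictor_set <- c("sex_expression", "leaf_habit", "fruit_type", "dbh95_cm")

#' Build a design matrix from a species-trait table
#'
#' Binary traits are coded 0/1: sex expression \code{dioecious = 1} (so the
#' intercept of a sex-only model is the cosexual mean), leaf habit
#' \code{evergreen = 1}, fruit type \code{fleshy = 1}. The 95th-percentile
#' stem diameter enters untransformed, in cm. An intercept column is always
#' included.
#'
#' @param traits A species-trait data frame ([read_trait_table()]).
#' @param predictors Character subset of \code{c("sex_expression",
#'   "leaf_habit", "fruit_type", "dbh95_cm")}.
#' @return A numeric design matrix with rownames the species labels
#'   (underscored) and an \code{"(Intercept)"} first column.
#' @export
design_matrix <- function(traits, predictors = .predictor_set) {
  bad <- setdiff(predictors, .predictor_set)
  if (length(bad) > 0L)
    stop("unknown predictor(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  n <- nrow(traits)
  X <- matrix(1, n, 1L, dimnames = list(species_label(traits$species),
                                        "(Intercept)"))
  cols <- list(
    sex_expression = function() as.numeric(traits$sex_expression == "dioecious"),
    leaf_habit     = function() as.numeric(traits$leaf_habit == "evergreen"),
    fruit_type     = function() as.numeric(traits$fruit_type == "fleshy"),
    dbh95_cm       = function() traits$dbh95_cm
  )
  for (p in .predictor_set)  # fixed order, independent of subset order
    if (p %in% predictors) X <- cbind(X, `colnames<-`(cbind(cols[[p]]()), p))
  X
}

#' Generalized least squares under a known covariance
#'
#' Fits \eqn{y = X\beta + e}, \eqn{e \sim N(0, \sigma^2 C)}:
#' \eqn{\hat\beta = (X'C^{-1}X)^{-1} X'C^{-1} y}. The log-likelihood uses
#' the ML variance \eqn{\hat\sigma^2 = e'C^{-1}e/n}; standard errors use
#' the unbiased variance (denominator \eqn{n - p}), and p-values are
#' two-sided from a t distribution with \eqn{n - p} degrees of freedom.
#'
#' @param y Response vector.
#' @param X Design matrix (include the intercept column).
#' @param C Covariance matrix (up to the scalar \eqn{\sigma^2}).
#' @return A list with \code{coefficients}, \code{std_errors},
#'   \code{t_values}, \code{p_values}, \code{sigma2_ml},
#'   \code{sigma2_unbiased}, \code{loglik}, \code{n}, \code{p} and
#'   \code{residuals}.
#' @export
gls_fit <- function(y, X, C) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  if (nrow(X) != n || nrow(C) != n)
    stop("y, X and C dimensions do not agree", call. = FALSE)
  if (qr(X)$rank < p)
    stop("design matrix is rank deficient; collinear column(s) among: ",
         paste(colnames(X), collapse = ", "), call. = FALSE)
  R <- tryCatch(chol(C), error = function(e)
    stop("covariance matrix is singular or not positive definite",
         call. = FALSE))
  logdet <- 2 * sum(log(diag(R)))
  # whiten: solve R' W = [X y]  =>  GLS becomes OLS on (Wx, wy)
  W <- backsolve(R, cbind(X, y), transpose = TRUE)
  Wx <- W[, seq_len(p), drop = FALSE]
  wy <- W[, p + 1L]
  XtX <- crossprod(Wx)
  beta <- drop(solve(XtX, crossprod(Wx, wy)))
  names(beta) <- colnames(X)
  resid <- y - drop(X %*% beta)
  rss <- sum((wy - drop(Wx %*% beta))^2)  # e' C^-1 e
  s2_ml <- rss / n
  s2_unb <- rss / (n - p)
  covb <- s2_unb * solve(XtX)
  se <- sqrt(diag(covb))
  names(se) <- colnames(X)
  tv <- beta / se
  pv <- 2 * stats::pt(abs(tv), df = n - p, lower.tail = FALSE)
  ll <- -0.5 * (n * log(2 * pi * s2_ml) + logdet + n)
  list(coefficients = beta, std_errors = se, t_values = tv, p_values = pv,
       sigma2_ml = s2_ml, sigma2_unbiased = s2_unb, loglik = ll,
       n = n, p = p, residuals = resid)
}

# Align the rows of (y, X) to the tip order of a covariance matrix.
align_design <- function(y, X, C) {
  if (!is.null(rownames(X)) && !is.null(rownames(C))) {
    miss <- setdiff(rownames(C), rownames(X))
    if (length(miss) > 0L)
      stop("no trait row for tip(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    idx <- match(rownames(C), rownames(X))
    X <- X[idx, , drop = FALSE]
    y <- y[idx]
  }
  list(y = y, X = X)
}

#' Phylogenetic regression under Pagel's lambda model
#'
#' Profiles \eqn{\lambda \in [0, 1]}: at each candidate lambda the
#' regression coefficients and variance are estimated by GLS on the
#' lambda-transformed covariance, and the ML lambda is found by bounded
#' scalar optimization (with both boundaries checked explicitly, so
#' \eqn{\hat\lambda} can be exactly 0 or 1). The reported AIC counts
#' \eqn{p + 2} parameters (coefficients, \eqn{\sigma^2}, \eqn{\lambda}).
#'
#' @param y Response vector, named by species label (or in tip order).
#' @param X Design matrix with species rownames ([design_matrix()]).
#' @param tree A calibrated (ultrametric) \code{"phylo"} tree, or a
#'   phylogenetic covariance matrix.
#' @param tol Optimizer tolerance (default 1e-8).
#' @return A list of class \code{"pgls_fit"}: the [gls_fit()] fields plus
#'   \code{lambda_hat}, \code{aic} and \code{k_params}.
#' @export
pgls_lambda <- function(y, X, tree, tol = 1e-8) {
  C <- if (inherits(tree, "phylo")) phylo_covariance(tree) else as.matrix(tree)
  if (is.null(names(y)) && !is.null(rownames(X))) names(y) <- rownames(X)
  al <- align_design(y, X, C)
  f <- function(l) gls_fit(al$y, al$X, lambda_transform(C, l))$loglik
  opt <- stats::optimize(f, interval = c(0, 1), maximum = TRUE, tol = tol)
  cand <- c(opt$maximum, 0, 1)
  ll <- c(opt$objective, f(0), f(1))
  l_hat <- cand[which.max(ll)]
  fit <- gls_fit(al$y, al$X, lambda_transform(C, l_hat))
  fit$lambda_hat <- l_hat
  fit$k_params <- fit$p + 2L
  fit$aic <- 2 * fit$k_params - 2 * fit$loglik
  class(fit) <- "pgls_fit"
  fit
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf("Phylogenetic regression (lambda model): n = %d, lambda = %.3g, lnL = %.3f, AIC = %.2f\n",
              x$n, x$lambda_hat, x$loglik, x$aic))
  tab <- cbind(Estimate = x$coefficients, `Std. error` = x$std_errors,
               `t value` = x$t_values, `P value` = x$p_values)
  print(signif(tab, 3L))
  invisible(x)
}

#' All-subsets model selection by AIC
#'
#' Fits the phylogenetic lambda-model regression of the response on every
#' subset of the four candidate predictors (2^4 = 16 models, intercept
#' always included) and ranks them by ascending AIC; ties are broken by
#' fewer parameters, then by the predictor names.
#'
#' @param traits A species-trait data frame with the response filled in.
#' @param tree A calibrated \code{"phylo"} tree (or covariance matrix)
#'   whose tips match the species.
#' @param response Response column (default \code{"s50"}).
#' @param predictors Candidate predictors (default all four).
#' @return A list of class \code{"subset_selection"}: \code{table} (a data
#'   frame with one row per subset: predictors, k_params, lambda_hat,
#'   loglik, aic, delta_aic, rank) and \code{fits} (the \code{"pgls_fit"}
#'   objects, in ranked order). \code{best_fit()} extracts the top model.
#' @export
all_subsets <- function(traits, tree, response = "s50",
                        predictors = .predictor_set) {
  y <- traits[[response]]
  if (is.null(y)) stop("response column not found: ", response, call. = FALSE)
  if (anyNA(y))
    stop("response has missing values for: ",
         paste(traits$species[is.na(y)], collapse = ", "), call. = FALSE)
  names(y) <- species_label(traits$species)
  subsets <- lapply(seq_len(2^length(predictors)) - 1L, function(m)
    predictors[bitwAnd(m, 2^(seq_along(predictors) - 1L)) > 0L])
  fits <- vector("list", length(subsets))
  errors <- character(0)
  for (i in seq_along(subsets)) {
    fits[i] <- list(tryCatch(
      pgls_lambda(y, design_matrix(traits, subsets[[i]]), tree),
      error = function(e) {
        errors <<- c(errors, paste0("{", paste(subsets[[i]], collapse = "+"),
                                    "}: ", conditionMessage(e)))
        NULL
      }))
  }
  ok <- !vapply(fits, is.null, NA)
  subsets <- subsets[ok]; fits <- fits[ok]
  lab <- vapply(subsets, function(s)
    if (length(s) == 0L) "(intercept only)" else
      paste(sort(s), collapse = " + "), "")
  tab <- data.frame(
    predictors = lab,
    k_params = vapply(fits, function(f) f$k_params, 0L),
    lambda_hat = vapply(fits, function(f) f$lambda_hat, 0),
    loglik = vapply(fits, function(f) f$loglik, 0),
    aic = vapply(fits, function(f) f$aic, 0),
    stringsAsFactors = FALSE
  )
  ord <- order(tab$aic, tab$k_params, tab$predictors)
  tab <- tab[ord, , drop = FALSE]
  fits <- fits[ord]
  tab$delta_aic <- tab$aic - tab$aic[1L]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  structure(list(table = tab, fits = fits, errors = errors),
            class = "subset_selection")
}

#' @rdname all_subsets
#' @param selection A \code{"subset_selection"} object.
#' @export
best_fit <- function(selection) selection$fits[[1L]]

#' @export
print.subset_selection <- function(x, ...) {
  cat("All-subsets phylogenetic regression, ranked by AIC:\n")
  tab <- x$table
  tab$lambda_hat <- signif(tab$lambda_hat, 3L)
  tab$loglik <- round(tab$loglik, 2L)
  tab$aic <- round(tab$aic, 2L)
  tab$delta_aic <- round(tab$delta_aic, 2L)
  print(tab, row.names = FALSE)
  if (length(x$errors) > 0L)
    cat("failed subsets:\n ", paste(x$errors, collapse = "\n  "), "\n")
  invisible(x)
}
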