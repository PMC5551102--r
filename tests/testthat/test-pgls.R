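test_that("the design matrix uses the documented 0/1 codings", {
  traits <- load_study_table()
  X <- design_matrix(traits)
  expect_equal(colnames(X), c("(Intercept)", "sex_expression", "leaf_habit",
                              "fruit_type", "dbh95_cm"))
  expect_equal(unname(X[traits$species == "Gamblea innovans", ]),
               c(1, 1, 0, 1, 30.3))  # dioecious, deciduous, fleshy
  expect_equal(unname(X[traits$species == "Camellia japonica", ]),
               c(1, 0, 1, 0, 33.1))  # cosexual, evergreen, dry
  # subset order does not change column order
  expect_equal(colnames(design_matrix(traits, c("dbh95_cm", "sex_expression"))),
               c("(Intercept)", "sex_expression", "dbh95_cm"))
  expect_error(design_matrix(traits, "growth_form"), "unknown predictor")
})

test_that("GLS reduces to OLS when the covariance is proportional to I", {
  expect_equal(unname(gls_fit(c(1, 2, 3), cbind(rep(1, 3)),
                              diag(3))$coefficients), 2)
  traits <- load_study_table()
  X <- design_matrix(traits, c("sex_expression", "dbh95_cm"))
  y <- traits$s50
  ols <- summary(lm(y ~ 0 + X))$coefficients
  for (T in c(0.01, 1, 137)) {
    fit <- gls_fit(y, X, T * diag(30))
    expect_equal(unname(fit$coefficients), unname(ols[, 1]),
                 tolerance = 1e-10)
    expect_equal(unname(fit$std_errors), unname(ols[, 2]),
                 tolerance = 1e-10)
    expect_equal(unname(fit$t_values), unname(ols[, 3]), tolerance = 1e-10)
    expect_equal(unname(fit$p_values), unname(ols[, 4]), tolerance = 1e-10)
  }
})

test_that("GLS matches hand matrix arithmetic on a 4-taxon tree", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  C <- phylo_covariance(tr)
  y <- c(A = 0.9, B = 1.4, C = 2.2, D = 2.9)
  X <- cbind("(Intercept)" = 1, grp = c(0, 0, 1, 1))
  rownames(X) <- names(y)
  Ci <- solve(C)
  beta_hand <- solve(t(X) %*% Ci %*% X, t(X) %*% Ci %*% y)
  fit <- gls_fit(y, X, C)
  expect_equal(unname(fit$coefficients), unname(drop(beta_hand)),
               tolerance = 1e-12)
  r <- y - drop(X %*% beta_hand)
  s2u <- drop(t(r) %*% Ci %*% r) / (4 - 2)
  se_hand <- sqrt(diag(s2u * solve(t(X) %*% Ci %*% X)))
  expect_equal(unname(fit$std_errors), unname(se_hand), tolerance = 1e-12)
  expect_error(gls_fit(y, cbind(X, grp2 = X[, 2]), C), "rank deficient")
})

test_that("GLS agrees with an independent Brownian-correlation fit", {
  skip_if_not_installed("nlme")
  tree <- random_ultra_tree(20, seed = 31)
  C <- phylo_covariance(tree)
  x1 <- precocity:::with_local_seed(32, stats::rnorm(20))
  y <- simulate_lambda_trait(tree, 1, 0.5, 1, seed = 33) + 0.8 * x1
  dat <- data.frame(y = as.numeric(y), x1 = x1, sp = tree$tip.label)
  ref <- nlme::gls(y ~ x1, data = dat, method = "ML",
                   correlation = ape::corBrownian(1, tree, form = ~sp))
  X <- cbind("(Intercept)" = 1, x1 = x1)
  rownames(X) <- tree$tip.label
  fit <- gls_fit(as.numeric(y), X, C)
  expect_equal(unname(fit$coefficients), unname(coef(ref)),
               tolerance = 1e-8)
  expect_equal(fit$loglik, as.numeric(stats::logLik(ref)), tolerance = 1e-6)
})

test_that("the lambda regression reproduces the sex-only study fit", {
  traits <- load_study_table()
  tree <- resolve_polytomies(
    bladj_calibrate(build_taxonomy_tree(traits, load_backbone()),
                    load_ages()), seed = 1)
  y <- stats::setNames(traits$s50, gsub(" ", "_", traits$species))
  fit <- pgls_lambda(y, design_matrix(traits, "sex_expression"), tree)
  expect_lt(fit$lambda_hat, 1e-6)
  expect_equal(unname(round(fit$coefficients, 3)), c(0.331, -0.166))
  expect_equal(unname(round(fit$t_values[2], 2)), -3.74)
  # with lambda at 0 on an ultrametric tree the coefficient is exactly the
  # difference of group means
  dio <- traits$sex_expression == "dioecious"
  expect_equal(unname(fit$coefficients[2]),
               mean(traits$s50[dio]) - mean(traits$s50[!dio]),
               tolerance = 1e-10)
  # AIC bookkeeping: k = p + 2 and aic = 2k - 2lnL
  expect_equal(fit$k_params, 4L)
  expect_equal(fit$aic, 2 * 4 - 2 * fit$loglik)
})

test_that("a true effect is recovered under Brownian residuals", {
  tree <- random_ultra_tree(64, seed = 41)
  grp <- precocity:::with_local_seed(42,
    sample(rep(c(0, 1), each = 32)))
  X <- cbind("(Intercept)" = 1, grp = grp)
  rownames(X) <- tree$tip.label
  betas <- vapply(1:100, function(i) {
    y <- simulate_lambda_trait(tree, 1, 0.5, 0, seed = 900 + i) + 1.0 * grp
    pgls_lambda(stats::setNames(y, tree$tip.label), X, tree)$coefficients[2]
  }, 0)
  expect_lt(abs(mean(betas) - 1.0), 0.1)
})

test_that("all-subsets selection ranks the study models as published", {
  traits <- load_study_table()
  tree <- resolve_polytomies(
    bladj_calibrate(build_taxonomy_tree(traits, load_backbone()),
                    load_ages()), seed = 1)
  sel <- all_subsets(traits, tree)
  expect_equal(nrow(sel$table), 16L)
  expect_equal(sel$table$predictors[1], "sex_expression")
  best <- best_fit(sel)
  expect_equal(best$aic, min(sel$table$aic))

  full <- sel$fits[[which(sel$table$k_params == 7L)]]
  expect_equal(signif(full$coefficients[["sex_expression"]], 3), -0.166)
  expect_lte(best$aic, full$aic)
  # every fit satisfies the AIC identity and has p-values in (0, 1]
  for (f in sel$fits) {
    expect_equal(f$aic, 2 * f$k_params - 2 * f$loglik)
    expect_true(all(f$p_values > 0 & f$p_values <= 1))
  }
})

test_that("the sex coefficient is invariant to the coding of other binaries", {
  traits <- load_study_table()
  tree <- bladj_calibrate(build_taxonomy_tree(traits, load_backbone()),
                          load_ages())
  C <- phylo_covariance(tree)
  y <- stats::setNames(traits$s50, gsub(" ", "_", traits$species))
  X <- design_matrix(traits)
  Xflip <- X
  Xflip[, "leaf_habit"] <- 1 - Xflip[, "leaf_habit"]
  Xflip[, "fruit_type"] <- 1 - Xflip[, "fruit_type"]
  f1 <- gls_fit(y[rownames(X)], X, C[rownames(X), rownames(X)])
  f2 <- gls_fit(y[rownames(X)], Xflip, C[rownames(X), rownames(X)])
  expect_equal(f1$coefficients[["sex_expression"]],
               f2$coefficients[["sex_expression"]], tolerance = 1e-12)
  expect_equal(f1$coefficients[["dbh95_cm"]], f2$coefficients[["dbh95_cm"]],
               tolerance = 1e-12)
  expect_equal(abs(f1$coefficients[["leaf_habit"]]),
               abs(f2$coefficients[["leaf_habit"]]), tolerance = 1e-12)
})

test_that("pure-noise responses make intercept-only the modal best model", {
  # With plain AIC a spurious predictor enters whenever its likelihood-ratio
  # improvement exceeds 2 (probability ~0.16 per predictor under the null),
  # so the intercept-only model wins roughly half the replicates - far above
  # the 1/16 chance level - and more often than any other single model.
  traits <- load_study_table()
  tree <- bladj_calibrate(build_taxonomy_tree(traits, load_backbone()),
                          load_ages())
  winners <- vapply(1:100, function(i) {
    noise <- traits
    noise$s50 <- precocity:::with_local_seed(1300 + i,
                                             stats::rnorm(30, 0.3, 0.1))
    all_subsets(noise, tree)$table$predictors[1]
  }, "")
  freq <- sort(table(winners), decreasing = TRUE)
  expect_equal(names(freq)[1], "(intercept only)")
  expect_gte(mean(winners == "(intercept only)"), 0.3)
})
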