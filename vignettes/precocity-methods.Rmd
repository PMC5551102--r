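---
title: "Methods: size at onset of flowering and its phylogenetic analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: size at onset of flowering and its phylogenetic analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(precocity)
```

This vignette documents the statistical models behind `precocity`, the
default parameter choices and why they were made, what the synthetic-data
generator does and does not emulate, and the package's known limitations.

## 1. The flowering-threshold model

Within a species, whether an individual bears flowers is modelled as a
Bernoulli outcome whose probability increases with *relative plant size*
`S`, the stem diameter divided by the species' estimated maximum diameter:

$$P(\text{flowering}) = \frac{e^{a + b\ln S}}{1 + e^{a + b\ln S}}.$$

This is a logistic regression of flowering on `ln S`; `a` is the log odds
of flowering at the species' maximum size (`S = 1`) and `b` measures how
sharply flowering switches on with size. Setting `P = 1/2` gives the
population-level onset of flowering,

$$S_{0.5} = \exp(-a/b),$$

which is well defined only when `b > 0` (flowering probability increasing
in size); `s50()` refuses `b <= 0` rather than returning a meaningless
number.

**Maximum size.** The divisor is the 95th percentile of the measured
diameters rather than the observed maximum, to be robust to single
outlying stems. `percentile95()` uses linear interpolation of order
statistics with index `h = (n - 1) * 0.95 + 1`, the default convention of
most statistical environments, so species-level values are reproducible
from raw diameters. A consequence worth knowing: about 5% of a sample
standardized by its own 95th percentile has `S > 1`, which is intentional.

**Fitting.** `fit_flowering_logistic()` maximizes the Bernoulli likelihood
by iteratively reweighted least squares (the binomial GLM engine), with a
relative deviance tolerance of `1e-10` and at most 100 iterations. These
are ordinary GLM settings; the tolerance is far below any biological
signal. Two degenerate regimes are handled explicitly:

- *All (or no) individuals flowering*: the likelihood has no interior
  maximum and no threshold is identified; this is an error, and batch
  estimation (`all_species_maturity(..., on_error = "omit")`) can drop
  such species with a warning instead — a species in which every surveyed
  individual flowered carries no information about its threshold.
- *Quasi-complete separation* (small plants all sterile, large all
  flowering, no overlap): the ML slope diverges. The fit is flagged
  (`separation_flag`) when any coefficient exceeds 50 in absolute value;
  `S0.5` is still usable (it converges to the separating size) but its
  scale parameters are not.

`species_maturity()` requires at least 20 records per species by default,
mirroring the field protocol the bundled data come from; the floor is an
argument, not a constant.

## 2. The taxonomy tree and its calibration

No molecular phylogeny is inferred. Species are grafted by taxonomy onto a
hand-written family backbone (18 families, consistent with an APG-III
ordinal topology): each family tip becomes a polytomy of its genera, each
genus a polytomy of its species, and single-descendant levels collapse.
This is the standard supertree shortcut for ecological comparative work:
topology above the family level is well established, while within-family
resolution is deliberately left as polytomies rather than guessed.

**Branch lengths** come from a table of approximate clade ages (Ma) by the
even-placement rule: named nodes found in the age table are fixed; every
other node takes an age by linear interpolation along the path between its
nearest calibrated ancestor and its nearest calibrated descendant (tips at
age 0, nearest measured in intervening nodes). Ages that violate
ancestor-descendant ordering raise a calibration-conflict error naming
both nodes. The result is ultrametric by construction, which the lambda
model assumes. The bundled ages are approximate; consequences are
discussed in section 6.

**Polytomies** are resolved to a random binary topology with zero-length
internal branches (`resolve_polytomies()`, seeded). Zero-length insertions
leave the phylogenetic covariance matrix unchanged — the tests assert this
— so every downstream statistic is invariant to the seed; resolution
exists only to satisfy tools that require binary trees.

**Covariance.** `phylo_covariance()` returns the Brownian-motion
covariance `C`: `C[i, j]` is the root-to-MRCA depth of tips `i` and `j`.
Pagel's transform `lambda_transform(C, lambda)` multiplies off-diagonal
entries by `lambda`, leaving the diagonal unchanged; for ultrametric `C`
the result stays positive semidefinite for all `lambda` in `[0, 1]`.

## 3. Phylogenetic signal

**Blomberg's K** compares the mean squared error of the trait about the
GLS mean computed as if tips were independent (`MSE0`) with the
phylogenetically corrected `MSE`, and scales their ratio by its Brownian
expectation on the same tree:

$$K = \frac{MSE_0 / MSE}{\left(\mathrm{tr}\,C - n / (\mathbf{1}'C^{-1}\mathbf{1})\right) / (n-1)}.$$

`K = 1` on any star phylogeny for any trait (the tests check this to
machine precision); `K < 1` means relatives resemble each other less than
Brownian motion predicts. Significance uses 999 permutations of trait
values across tips by default, with the phylogenetic MSE as the test
statistic (smaller = more signal) and the observed arrangement included in
the null set, so p is a multiple of 1/1000 and is bit-reproducible given
the seed. K itself and the MSE order permutations identically, so the
choice between them does not change p.

**Pagel's λ** is estimated by maximizing the profile normal
log-likelihood over `lambda` in `[0, 1]` — the root state and the rate
`sigma^2` have closed-form GLS solutions at each lambda, so the problem is
one-dimensional and solved by bounded scalar optimization (tolerance
`1e-8`), with both boundaries evaluated explicitly so the estimate can be
exactly 0 or 1. The significance test is a likelihood-ratio test of
`lambda = 0` (no signal) against a chi-squared with 1 df. The null could
alternatively be taken as `lambda = 1`; testing `lambda = 0` is the
reading consistent with reporting "signal present/absent", and both
log-likelihoods are returned so the other test is one subtraction away.
Because `lambda = 0` is a boundary, the chi-squared reference is
conservative; the tests verify the type-I error stays at or below nominal.
The search is restricted to `[0, 1]`: values above 1 can make the
covariance non-positive-definite and have no generative interpretation
here.

ML rather than REML is used throughout, matching the regression module (a
model-selection exercise, where REML likelihoods are not comparable across
fixed-effect structures).

## 4. Phylogenetic regression and model selection

`gls_fit()` is textbook GLS via a Cholesky whitening of `C`:
`beta = (X'C^-1X)^-1 X'C^-1 y`. Two variance estimates coexist by design:
the ML variance `e'C^-1e/n` enters the log-likelihood and hence AIC, while
standard errors, t and p values use the unbiased variance (denominator
`n - p`), which is what practitioners compare against published regression
tables. `pgls_lambda()` profiles `lambda` exactly as in section 3 and
counts `p + 2` parameters (coefficients, variance, lambda) in
`AIC = 2k - 2 lnL`.

Binary predictors are coded dioecious = 1, evergreen = 1, fleshy = 1, with
the intercept therefore the cosexual/deciduous/dry baseline; maximum DBH
enters untransformed in cm. The codings are documented in
`design_matrix()` and the sex coefficient is invariant to how the other
binaries are coded (only the intercept shifts; the tests assert this).

`all_subsets()` fits all 16 predictor subsets (intercept always included),
re-estimating `lambda` in each — on the bundled data every subset drives
`lambda` to 0, so whether `lambda` is re-estimated or fixed from the full
model is immaterial there. Ties in AIC break toward fewer parameters, then
lexicographic predictor names, making the ranking deterministic.

A property of the `lambda -> 0` limit worth stating: on an ultrametric
tree `C_0` is proportional to the identity, so the fit — coefficients,
SEs, t values — is numerically identical to OLS and therefore independent
of the tree's age scale. This is why the bundled study's coefficient table
is exactly reproducible even though the original calibrated tree is not:
only quantities that depend on `|C|`'s absolute scale (the likelihood and
AIC values themselves) vary with the age table, and only AIC *orderings*
are asserted.

**Selection behaviour under a null.** With plain AIC a spurious predictor
is admitted whenever its likelihood-ratio improvement exceeds 2, which
happens with probability about 0.16 per predictor under the null; with
four candidates the intercept-only model therefore wins only about half of
null replicates. This is an inherent property of AIC selection, not a
defect of the implementation; the test suite asserts the intercept-only
model is the modal winner, far above the 1/16 chance level.

## 5. The synthetic-data generator

`make_synthetic_study()` produces a complete study with known truth:

1. a Yule (pure-birth) tree (`ape`'s constant-rate simulator, seeded);
2. a baseline threshold trait drawn from
   `N(root_state, sigma2 * C_lambda)`;
3. a binary "dioecious" state assigned to a seeded random subset of
   species — random rather than evolved, because sex expression is treated
   as a fixed species attribute, not a trait whose evolution is modelled;
4. true thresholds `s50 = baseline + effect_size * dioecious`, clipped to
   `(0.02, 0.98)` to keep the logistic fits identifiable;
5. per-species records: diameters log-uniform over `(0.05, 1.2) * dbh95`
   (even coverage of the size range on the log scale the model uses, since
   the emulated survey deliberately spanned all size classes), flowering
   Bernoulli from the logistic model with `a = -b ln s50`.

Defaults mirror the bundled study: 30 species, 11/30 dioecious, effect
−0.166, baseline 0.33, weak signal (`lambda = 0.1`), about 60 records per
species, logistic slopes uniform on (3, 8) around the worked example's
4.8. The Brownian rate default `sigma2 = 0.002` gives tip standard
deviations near 0.09 on a 30–60 tip Yule tree (height of order `log n`),
within the bundled study's within-group spread (0.073–0.136), while
keeping clipped thresholds rare. Species whose simulated records are
all-flowered (true threshold below the surveyed size range, an artefact of
clipping) are omitted from the validation pipeline with a warning.

**What the generator does not emulate:** real diameter distributions
(usually reverse-J shaped, not log-uniform), measurement error in
diameters, sex-ratio structure within dioecious species, non-flowering
years of mature individuals, spatial or observer effects, or correlated
evolution between the binary traits and the threshold. Passing recovery
tests therefore show the estimators are consistent under their own model
assumptions — not that those assumptions hold in any particular forest.

## 6. Problem sizes, numerical choices and limitations

The test suite's simulation sizes are chosen to give stable Monte-Carlo
checks at interactive run times: 200 species for threshold-recovery bias,
100 replicates for lambda recovery (128 tips) and effect recovery (60
species, 300 records each), 500 replicates for the permutation type-I
error, 2,000 for trait-covariance checks.

Numerical details: covariance solves use Cholesky factorization and fail
loudly on non-positive-definite input; the lambda profile is continuous on
`[0, 1]` and its optimizer is bracketed with explicit boundary checks;
all randomness flows through a seed-scoped RNG helper that restores the
caller's RNG state, so generators are pure functions of (configuration,
seed).

Limitations to keep in mind:

- The bundled backbone and ages are approximate. Quantities that survive
  this (because `lambda -> 0` reduces to OLS) are the regression
  coefficient tables and AIC orderings; quantities that do not are the
  point values of K and lambda, which shift with tree shape and age scale.
  On the bundled tree the signal tests agree qualitatively (both
  non-significant for `S0.5`) with analyses on other calibrations, but
  their point values should not be compared across trees.
- No confidence intervals on `S0.5` are provided, and no sex-specific
  thresholds within dioecious species.
- The lambda model is the only correlation structure offered (no
  Ornstein-Uhlenbeck or early-burst), and interactions among predictors
  are not fitted.
- Phylogenetic signal statistics are for continuous traits only.
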