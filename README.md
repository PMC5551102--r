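# precocity

Tools for asking whether dioecious woody plants begin flowering at smaller
relative sizes than cosexual ones, and for the comparative machinery that
question needs.

Many dioecious trees and shrubs carry two reproductive handicaps: they
cannot self-pollinate, and only half the population sets seed. One candidate
compensation is precocity — flowering at a smaller fraction of final size,
which raises the density of reproductive individuals. Testing this across
species requires (i) a per-species estimate of the size threshold of
flowering, (ii) a phylogeny, because species are not independent data
points, and (iii) a regression that accounts for that non-independence.
`precocity` implements all three stages for individual-level survey data,
plus a synthetic-data generator so every stage has a parameter-recovery
test.

## The model

For each species, flowering status is modelled against relative plant size
`S` (stem diameter divided by the species' 95th-percentile diameter) with a
logistic curve:

    P(flowering) = exp(a + b ln S) / (1 + exp(a + b ln S))

The size at which half the individuals flower is `S0.5 = exp(-a / b)`.

Species-level `S0.5` values are then analysed on a calibrated
taxonomy-based tree (species grafted onto a family backbone; branch
lengths from a node-age table by bladj-style even placement):

- **Phylogenetic signal**: Blomberg's K with a permutation test, and
  Pagel's λ by maximum likelihood with a likelihood-ratio test.
- **Phylogenetic regression**: GLS under the λ covariance model
  (`C_λ` multiplies off-diagonal covariances by λ), with all 2⁴ subsets of
  the predictors {sex expression, leaf habit, fruit type, max DBH} ranked
  by AIC.

A 30-species trait table from a temperate evergreen broad-leaved forest is
bundled, together with an 18-family backbone and clade ages.

## Worked example

```r
library(precocity)
rep <- run_study_reproduction(n_perm = 999, seed = 1)
print(rep)
```

prints

```
S0.5 by sex expression:
 sex_expression  n mean_s50 sd_s50
       cosexual 19    0.331  0.136
      dioecious 11    0.165  0.073

Phylogenetic signal of S0.5:
  Blomberg's K = 0.788, P = 0.089 (999 permutations)
  Pagel's lambda = 0.386, P = 0.673 (LRT vs lambda = 0)

Best model by AIC (sex_expression):
Phylogenetic regression (lambda model): n = 30, lambda = 0, lnL = 22.801, AIC = -37.60
               Estimate Std. error t value  P value
(Intercept)       0.331     0.0269   12.30 8.02e-13
sex_expression   -0.166     0.0444   -3.74 8.34e-04
```

Read: dioecious species flower at about half the relative size of cosexual
species (0.165 vs 0.331). `S0.5` itself shows no significant phylogenetic
signal on this tree, the ML λ of the regression residuals collapses to 0,
and among all 16 predictor subsets AIC retains sex expression alone, with a
dioecy effect of −0.166 (t = −3.74).

Per-species estimation from raw records uses the same machinery:

```r
obs <- simulate_species_observations(0.216, 4.812, 30.3, 500, seed = 42,
                                     species_id = "demo")
species_maturity(obs, "demo")
#> demo: S0.5 = 0.215 (dbh95 = 30.6 cm, n = 500)
```

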