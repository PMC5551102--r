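Package: precocity
Title: Relative Size at Onset of Flowering in Woody Plants, with
    Phylogenetic Comparative Tests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates, per species, the relative plant size at which half of
    the individuals in a population flower (S0.5) from individual flowering
    records via a logistic model in log relative size; builds a calibrated
    taxonomy-based phylogeny from a family backbone and a node-age table;
    quantifies phylogenetic signal of continuous traits with Blomberg's K
    (permutation test) and Pagel's lambda (likelihood-ratio test); and fits
    phylogenetic linear regressions under the lambda covariance model with
    exhaustive subset selection by AIC. Includes a synthetic-study generator
    (Yule trees, lambda-transformed Brownian traits, simulated flowering
    records) so every stage has a parameter-recovery test, and a bundled
    species-trait table for a 30-species temperate woody flora.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    jsonlite,
    MASS
Suggests:
    testthat (>= 3.0.0),
    phytools,
    nlme,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
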