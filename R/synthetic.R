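#' Configuration for a synthetic flowering study
#'
#' Bundles the parameters of the generator. Defaults emulate the bundled
#' 30-species study: about a third of species dioecious, a dioecy effect of
#' -0.166 on the flowering threshold, weak phylogenetic signal
#' (lambda = 0.1), a cosexual baseline threshold of 0.33, and roughly 60
#' individuals surveyed per species.
#'
#' @param n_species Number of species (tips), >= 3.
#' @param birth_rate Speciation rate of the Yule tree.
#' @param lambda_true Pagel's lambda of the baseline threshold trait.
#' @param sigma2 Brownian rate of the baseline trait (per unit branch
#'   length; Yule trees here have height of order log(n_species), so the
#'   default gives tip standard deviations near 0.09, in the range of the
#'   study's within-group spread).
#' @param root_state Baseline (cosexual) threshold at the root.
#' @param binary_fraction Fraction of species assigned the binary state
#'   (dioecious), in (0, 1).
#' @param effect_size Additive effect of the binary state on the true
#'   threshold (the study-scale value is -0.166).
#' @param logistic_b_range Range from which each species' logistic slope b
#'   is drawn uniformly.
#' @param per_species_n Individuals surveyed per species.
#' @param seed Integer seed; all generator output is a pure function of
#'   the configuration including this seed.
#' @return A list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_species = 30L, birth_rate = 1, lambda_true = 0.1,
                       sigma2 = 0.002, root_state = 0.33,
                       binary_fraction = 11 / 30, effect_size = -0.166,
                       logistic_b_range = c(3, 8), per_species_n = 60L,
                       seed = 1L) {
  stopifnot(n_species >= 3L, birth_rate > 0,
            lambda_true >= 0, lambda_true <= 1, sigma2 > 0,
            binary_fraction > 0, binary_fraction < 1,
            length(logistic_b_range) == 2L, all(logistic_b_range > 0),
            logistic_b_range[1L] <= logistic_b_range[2L],
            per_species_n >= 1L)
  structure(list(n_species = as.integer(n_species), birth_rate = birth_rate,
                 lambda_true = lambda_true, sigma2 = sigma2,
                 root_state = root_state, binary_fraction = binary_fraction,
                 effect_size = effect_size,
                 logistic_b_range = logistic_b_range,
                 per_species_n = as.integer(per_species_n),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a pure-birth (Yule) tree
#'
#' @param n_species Number of tips (>= 2).
#' @param birth_rate Speciation rate.
#' @param seed Integer seed.
#' @return An ultrametric binary \code{"phylo"} tree with tips
#'   \code{sp01, sp02, ...}.
#' @export
simulate_yule_tree <- function(n_species, birth_rate = 1, seed = 1L) {
  if (n_species < 2L) stop("need at least 2 species", call. = FALSE)
  tr <- with_local_seed(seed,
                        ape::rphylo(n_species, birth = birth_rate, death = 0))
  tr$tip.label <- sprintf("sp%0*d", max(2L, nchar(n_species)),
                          seq_len(n_species))
  tr
}

#' Simulate a continuous trait under lambda-transformed Brownian motion
#'
#' Draws one realization from a multivariate normal with mean
#' \code{root_state} and covariance \code{sigma2} times the
#' lambda-transformed phylogenetic covariance of the tree.
#'
#' @param tree An ultrametric \code{"phylo"} tree.
#' @param lambda_true Pagel's lambda in [0, 1].
#' @param sigma2 Brownian rate.
#' @param root_state Mean (ancestral state).
#' @param seed Integer seed.
#' @return A numeric vector named by tip label.
#' @export
simulate_lambda_trait <- function(tree, lambda_true, sigma2, root_state = 0,
                                  seed = 1L) {
  C <- lambda_transform(phylo_covariance(tree), lambda_true)
  x <- with_local_seed(seed,
    MASS::mvrnorm(1L, mu = rep(root_state, nrow(C)), Sigma = sigma2 * C))
  names(x) <- rownames(C)
  x
}

#' Simulate individual flowering records for one species
#'
#' Stem diameters are drawn log-uniformly over (0.05, 1.2) times the
#' species' maximum diameter, so all size classes are represented on the
#' log scale the model uses; flowering is Bernoulli with probability
#' \eqn{logit^{-1}(a + b \ln(d / dbh95))} where \eqn{a = -b \ln S_{0.5}}.
#'
#' @param s50_true True relative threshold size, in (0, 1].
#' @param b Logistic slope (> 0; larger = sharper threshold).
#' @param dbh95 The species' 95th-percentile diameter (cm).
#' @param per_species_n Number of individuals.
#' @param seed Integer seed.
#' @param species_id Species name for the output rows.
#' @return An observation data frame ([read_observations()] schema).
#' @export
simulate_species_observations <- function(s50_true, b, dbh95, per_species_n,
                                          seed = 1L, species_id = "sp") {
  stopifnot(s50_true > 0, b > 0, dbh95 > 0, per_species_n >= 1L)
  with_local_seed(seed, {
    d <- exp(stats::runif(per_species_n, log(0.05 * dbh95),
                          log(1.2 * dbh95)))
    eta <- -b * log(s50_true) + b * log(d / dbh95)
    fl <- stats::rbinom(per_species_n, 1L, stats::plogis(eta)) == 1L
    data.frame(species = species_id, diameter_cm = d, flowered = fl,
               sex = "unknown", stringsAsFactors = FALSE)
  })
}

#' Generate a complete synthetic study
#'
#' Produces a Yule tree, a species-trait table and an individual-level
#' observation table with fully known parameters: a baseline threshold
#' trait evolves under lambda-transformed Brownian motion, a binary state
#' (dioecious) is assigned to a seeded random subset of species and shifts
#' the true threshold additively, and flowering records are drawn from the
#' logistic model per species. True thresholds are clipped to (0.02, 0.98)
#' to keep the logistic fits identifiable.
#'
#' @param config A [sim_config()] object.
#' @return A list with \code{observations}, \code{traits} (the trait table
#'   with \code{s50} left \code{NA}, to be filled by the estimation
#'   pipeline), \code{tree} and \code{truth} (every generating parameter,
#'   including per-species \code{s50_true}, \code{b} and \code{dbh95_cm}).
#' @export
make_synthetic_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  tree <- simulate_yule_tree(cfg$n_species, cfg$birth_rate, cfg$seed)
  baseline <- simulate_lambda_trait(tree, cfg$lambda_true, cfg$sigma2,
                                    cfg$root_state, cfg$seed + 1L)
  n_bin <- ceiling(cfg$binary_fraction * cfg$n_species)
  aux <- with_local_seed(cfg$seed + 2L, {
    dio <- sample(tree$tip.label, n_bin)
    dbh95 <- exp(stats::runif(cfg$n_species, log(5), log(60)))
    b <- stats::runif(cfg$n_species, cfg$logistic_b_range[1L],
                      cfg$logistic_b_range[2L])
    leaf <- sample(.leaf_levels, cfg$n_species, replace = TRUE)
    fruit <- sample(.fruit_levels, cfg$n_species, replace = TRUE)
    list(dio = dio, dbh95 = dbh95, b = b, leaf = leaf, fruit = fruit)
  })
  is_dio <- tree$tip.label %in% aux$dio
  s50_true <- pmin(pmax(baseline + cfg$effect_size * is_dio, 0.02), 0.98)
  obs <- do.call(rbind, lapply(seq_len(cfg$n_species), function(i)
    simulate_species_observations(s50_true[[i]], aux$b[i], aux$dbh95[i],
                                  cfg$per_species_n, cfg$seed + 2L + i,
                                  tree$tip.label[i])))
  traits <- data.frame(
    species = tree$tip.label,
    family = "SimFam",
    genus = tree$tip.label,
    s50 = NA_real_,
    sex_expression = ifelse(is_dio, "dioecious", "cosexual"),
    leaf_habit = aux$leaf,
    fruit_type = aux$fruit,
    dbh95_cm = aux$dbh95,
    n_obs = cfg$per_species_n,
    stringsAsFactors = FALSE
  )
  list(observations = obs, traits = traits, tree = tree,
       truth = list(config = cfg, s50_true = stats::setNames(s50_true,
                                                             tree$tip.label),
                    b = stats::setNames(aux$b, tree$tip.label),
                    dbh95_cm = stats::setNames(aux$dbh95, tree$tip.label),
                    dioecious = sort(aux$dio)))
}
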