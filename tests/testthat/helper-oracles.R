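# Independent oracles and small fixtures used across the test files.

# Bernoulli log-likelihood of the logistic flowering model.
logistic_loglik <- function(a, b, sizes, flowered) {
  eta <- a + b * log(sizes)
  sum(ifelse(flowered, eta, 0) - log1p(exp(eta)))
}

# Brute-force ML for (a, b): coarse grid then iterative local refinement.
# Deliberately knows nothing about IRLS.
grid_logistic_ml <- function(sizes, flowered,
                             a_range = c(-20, 20), b_range = c(-20, 20)) {
  best <- c(a = 0, b = 0)
  width_a <- diff(a_range) / 2
  width_b <- diff(b_range) / 2
  centre <- c(mean(a_range), mean(b_range))
  for (iter in 1:40) {
    a_grid <- seq(centre[1] - width_a, centre[1] + width_a, length.out = 21)
    b_grid <- seq(centre[2] - width_b, centre[2] + width_b, length.out = 21)
    ll <- outer(a_grid, b_grid,
                Vectorize(function(a, b) logistic_loglik(a, b, sizes, flowered)))
    idx <- arrayInd(which.max(ll), dim(ll))
    centre <- c(a_grid[idx[1]], b_grid[idx[2]])
    width_a <- width_a / 4
    width_b <- width_b / 4
  }
  c(a = centre[1], b = centre[2])
}

# Grid argmax of the lambda profile log-likelihood (closed-form normal
# likelihood evaluated by plain dense linear algebra).
grid_lambda_ml <- function(x, C, step = 1e-3) {
  lams <- seq(0, 1, by = step)
  ll <- vapply(lams, function(l) {
    Cl <- l * C
    diag(Cl) <- diag(C)
    n <- length(x)
    Ci <- solve(Cl)
    one <- rep(1, n)
    a <- sum(Ci %*% x) / sum(Ci %*% one)
    r <- x - a
    s2 <- drop(t(r) %*% Ci %*% r) / n
    -0.5 * (n * log(2 * pi * s2) + determinant(Cl)$modulus + n)
  }, 0)
  list(lambda = lams[which.max(ll)], loglik = max(ll))
}

# A fixed 10-point toy data set for the logistic oracle comparison.
toy_logistic <- list(
  sizes = c(0.08, 0.12, 0.18, 0.25, 0.33, 0.42, 0.55, 0.70, 0.85, 1.05),
  flowered = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE)
)

# Chain tree root -> n1 -> n2 -> tip, built by hand (ape's newick reader
# does not round-trip singleton chains).
chain_tree <- function() {
  structure(list(
    edge = matrix(c(2L, 3L, 3L, 4L, 4L, 1L), ncol = 2, byrow = TRUE),
    tip.label = "tip",
    node.label = c("root", "n1", "n2"),
    Nnode = 3L
  ), class = "phylo", order = "cladewise")
}

# Root-to-node ages recomputed from branch lengths, named where labelled.
# Walks the edge list directly so singleton chains are handled too.
ages_from_lengths <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  depth <- rep(NA_real_, n_all)
  depth[n_tip + 1L] <- 0
  while (anyNA(depth)) {
    for (e in seq_len(nrow(tree$edge))) {
      p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
      if (!is.na(depth[p]))
        depth[ch] <- depth[p] + tree$edge.length[e]
    }
  }
  ages <- max(depth) - depth
  names(ages) <- c(tree$tip.label,
                   if (is.null(tree$node.label)) rep("", tree$Nnode)
                   else tree$node.label)
  ages
}

# A small random ultrametric tree (coalescent), seeded.
random_ultra_tree <- function(n, seed) {
  precocity:::with_local_seed(seed, ape::rcoal(n))
}
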