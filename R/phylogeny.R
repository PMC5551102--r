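#' Read a family backbone topology
#'
#' @param path Path to a newick file whose tips are family names and whose
#'   internal nodes may carry clade labels used for age calibration.
#' @return An \code{ape} \code{"phylo"} object.
#' @export
read_backbone <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse newick file: ", path, call. = FALSE)
  tr
}

#' Read a node-age table
#'
#' @param path Path to a CSV with columns \code{clade} and \code{age}
#'   (arbitrary time units, larger = older).
#' @return A named numeric vector of ages.
#' @export
read_ages <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("clade", "age") %in% names(d)))
    stop("age table needs columns 'clade' and 'age'", call. = FALSE)
  ages <- as.numeric(d$age)
  if (any(!is.finite(ages) | ages <= 0))
    stop("ages must be strictly positive", call. = FALSE)
  names(ages) <- as.character(d$clade)
  ages
}

#' Bundled family backbone and node ages for the 30-species study
#'
#' The backbone is a hand-written newick over the study's 18 families,
#' consistent with an APG-III ordinal topology; the age table holds
#' approximate crown ages (Ma) for the named backbone clades. Both are
#' plain-text fixtures shipped with the package.
#'
#' @return \code{load_backbone()}: a \code{"phylo"} object with 18 family
#'   tips; \code{load_ages()}: a named numeric vector of clade ages.
#' @export
load_backbone <- function() {
  read_backbone(system.file("extdata", "family_backbone.nwk",
                            package = "precocity", mustWork = TRUE))
}

#' @rdname load_backbone
#' @export
load_ages <- function() {
  read_ages(system.file("extdata", "node_ages.csv",
                        package = "precocity", mustWork = TRUE))
}

# newick-safe species label
species_label <- function(x) gsub(" ", "_", x)

#' Graft species onto a family backbone by taxonomy
#'
#' Replaces each family tip of the backbone with a polytomy of its genera,
#' and each genus with a polytomy of its species, as in taxonomy-based
#' supertree assembly. Families or genera with a single descendant collapse
#' to that tip. Internal nodes are labelled with the family (or genus) name
#' so that ages can later be attached by name.
#'
#' @param traits A species-trait data frame with \code{species},
#'   \code{family} and \code{genus} columns ([read_trait_table()]).
#' @param backbone A \code{"phylo"} backbone whose tips are family names.
#' @return A \code{"phylo"} tree whose tips are the species (spaces replaced
#'   by underscores), without branch lengths.
#' @export
build_taxonomy_tree <- function(traits, backbone) {
  fams <- unique(traits$family)
  missing <- setdiff(fams, backbone$tip.label)
  if (length(missing) > 0L)
    stop("family not found in backbone: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (nrow(traits) == 1L)
    return(ape::read.tree(text = paste0("(", species_label(traits$species), ");")))
  bb <- if (length(fams) < length(backbone$tip.label))
    ape::keep.tip(backbone, fams) else backbone
  nwk <- ape::write.tree(bb)
  for (fam in fams) {
    rows <- traits[traits$family == fam, , drop = FALSE]
    nwk <- sub(paste0("([(,])", fam, "([,):;])"),
               paste0("\\1", family_clade_string(rows), "\\2"), nwk)
  }
  tr <- ape::read.tree(text = nwk)
  if (length(tr$tip.label) != nrow(traits))
    stop("internal error: grafted tree has ", length(tr$tip.label),
         " tips for ", nrow(traits), " species", call. = FALSE)
  tr
}

# newick fragment for one family's species, grouped by genus
family_clade_string <- function(rows) {
  if (nrow(rows) == 1L) return(species_label(rows$species))
  genera <- split(rows, rows$genus)
  parts <- vapply(names(genera), function(g) {
    sp <- species_label(genera[[g]]$species)
    if (length(sp) == 1L) sp else
      paste0("(", paste(sp, collapse = ","), ")", g)
  }, "")
  if (length(parts) == 1L)  # single genus: name the node by the family
    sub(paste0(")", names(genera)), paste0(")", rows$family[1L]),
        parts, fixed = TRUE)
  else
    paste0("(", paste(parts, collapse = ","), ")", rows$family[1L])
}

# ages of all nodes measured from the tips (root = tree height), from
# branch lengths; assumes ultrametric input for the age interpretation
node_ages <- function(tree) {
  depths <- ape::node.depth.edgelength(tree)
  max(depths) - depths
}

#' Calibrate branch lengths from a node-age table
#'
#' Assigns ages to internal nodes whose labels appear in \code{ages}; every
#' other internal node receives an age by even spacing along the path
#' between its nearest calibrated ancestor and its nearest calibrated
#' descendant (tips have age 0). Branch lengths are then parent age minus
#' child age, so the result is ultrametric. This is the even-placement rule
#' of bladj-style calibration.
#'
#' @param tree A rooted \code{"phylo"} tree; the root's label must be
#'   present in \code{ages}.
#' @param ages Named numeric vector of clade ages ([read_ages()]).
#' @return The tree with branch lengths assigned (ultrametric).
#' @export
bladj_calibrate <- function(tree, ages) {
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  root <- n_tip + 1L
  labels <- tree$node.label
  if (is.null(labels)) labels <- rep("", n_node)
  age <- rep(NA_real_, n_tip + n_node)
  age[seq_len(n_tip)] <- 0
  known <- rep(FALSE, n_tip + n_node)  # fixed by the age table (or a tip)
  known[seq_len(n_tip)] <- TRUE
  for (i in seq_len(n_node)) {
    lb <- labels[i]
    if (nzchar(lb) && lb %in% names(ages)) {
      age[n_tip + i] <- ages[[lb]]
      known[n_tip + i] <- TRUE
    }
  }
  if (!known[root])
    stop("the root node ('", labels[1L],
         "') must be present in the age table", call. = FALSE)
  children <- split(tree$edge[, 2L], tree$edge[, 1L])
  parent <- integer(n_tip + n_node)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  node_name <- function(k)
    if (k <= n_tip) tree$tip.label[k] else
      if (nzchar(labels[k - n_tip])) labels[k - n_tip] else paste0("node#", k)
  # conflict check among fixed ages: every fixed descendant must be younger
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    a <- p
    while (TRUE) {
      if (known[a] && known[ch] && !is.na(age[a]) && age[ch] >= age[a])
        stop("calibration conflict: '", node_name(ch), "' (age ", age[ch],
             ") is not younger than its ancestor '", node_name(a), "' (age ",
             age[a], ")", call. = FALSE)
      if (known[a] || a == root) break
      a <- parent[a]
    }
  }
  # steps down to the nearest fixed-age descendant (tips count, age 0)
  nearest_fixed_below <- function(node) {
    frontier <- children[[as.character(node)]]
    steps <- 1L
    repeat {
      hit <- frontier[known[frontier]]
      if (length(hit) > 0L) return(list(steps = steps, age = min(age[hit])))
      frontier <- unlist(children[as.character(frontier)], use.names = FALSE)
      steps <- steps + 1L
    }
  }
  # preorder: parents are aged before children, so even spacing falls out
  ord <- root
  queue <- children[[as.character(root)]]
  while (length(queue) > 0L) {
    nd <- queue[[1L]]; queue <- queue[-1L]
    ord <- c(ord, nd)
    if (nd > n_tip) queue <- c(queue, children[[as.character(nd)]])
  }
  for (nd in ord) {
    if (nd <= n_tip || known[nd]) next
    p_age <- age[parent[nd]]
    nf <- nearest_fixed_below(nd)
    age[nd] <- p_age - (p_age - nf$age) / (nf$steps + 1L)
  }
  tree$edge.length <- age[tree$edge[, 1L]] - age[tree$edge[, 2L]]
  if (any(tree$edge.length < 0))
    stop("calibration produced a negative branch length", call. = FALSE)
  tree
}

#' Resolve polytomies into a binary tree
#'
#' Multichotomies are resolved to a random rooted binary topology by
#' inserting internal branches of length zero, so root-to-tip distances and
#' the phylogenetic covariance matrix are unchanged. Deterministic given
#' \code{seed}.
#'
#' @param tree A \code{"phylo"} tree with branch lengths.
#' @param seed Integer seed (default 1).
#' @return A binary \code{"phylo"} tree.
#' @export
resolve_polytomies <- function(tree, seed = 1L) {
  if (ape::is.binary.phylo(tree)) return(tree)
  with_local_seed(seed, ape::multi2di(tree, random = TRUE))
}

# run code under a fixed RNG seed without disturbing the caller's stream
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Phylogenetic covariance matrix
#'
#' The expected trait covariance under Brownian motion: entry (i, j) is the
#' depth (from the root) of the most recent common ancestor of tips i and
#' j, and the diagonal holds root-to-tip distances.
#'
#' @param tree A \code{"phylo"} tree with branch lengths.
#' @return An n x n symmetric matrix with tip labels as dimnames.
#' @export
phylo_covariance <- function(tree) {
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; calibrate it first", call. = FALSE)
  ape::vcv.phylo(tree)
}

#' Pagel's lambda transform of a covariance matrix
#'
#' Multiplies the off-diagonal entries of a phylogenetic covariance matrix
#' by \code{lambda}, leaving the diagonal unchanged: \code{lambda = 1} is
#' plain Brownian motion, \code{lambda = 0} removes all phylogenetic
#' correlation (a star phylogeny).
#'
#' @param C A phylogenetic covariance matrix.
#' @param lambda A value in [0, 1].
#' @return The transformed matrix.
#' @export
lambda_transform <- function(C, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0 || lambda > 1)
    stop("lambda must be a single value in [0, 1]", call. = FALSE)
  Cl <- C * lambda
  diag(Cl) <- diag(C)
  Cl
}
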