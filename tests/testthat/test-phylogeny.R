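test_that("taxonomy grafting reproduces the study's tree structure", {
  traits <- load_study_table()
  tree <- build_taxonomy_tree(traits, load_backbone())
  expect_equal(length(tree$tip.label), 30L)
  expect_setequal(tree$tip.label, gsub(" ", "_", traits$species))

  # the five Lauraceae species form one clade spanning four genera
  lau_node <- which(tree$node.label == "Lauraceae") + length(tree$tip.label)
  lau <- ape::extract.clade(tree, lau_node)
  expect_equal(length(lau$tip.label), 5L)
  genera <- unique(sub("_.*", "", lau$tip.label))
  expect_equal(sort(genera),
               c("Cinnamomum", "Litsea", "Machilus", "Neolitsea"))

  # congeners are sisters: the two Magnolia species form a cherry
  mag_node <- which(tree$node.label == "Magnoliaceae") +
    length(tree$tip.label)
  mag <- ape::extract.clade(tree, mag_node)
  expect_setequal(mag$tip.label,
                  c("Magnolia_obovata", "Magnolia_salicifolia"))
})

test_that("taxonomy grafting handles degenerate and invalid inputs", {
  traits <- load_study_table()
  one <- traits[traits$species == "Camellia japonica", , drop = FALSE]
  tr <- build_taxonomy_tree(one, load_backbone())
  expect_equal(tr$tip.label, "Camellia_japonica")

  bad <- traits
  bad$family[5] <- "Pinaceae"
  expect_error(build_taxonomy_tree(bad, load_backbone()), "Pinaceae")
})

test_that("age calibration spaces uncalibrated nodes evenly", {
  tr <- chain_tree()
  out <- bladj_calibrate(tr, c(root = 90))
  ages <- ages_from_lengths(out)
  expect_equal(unname(ages[c("root", "n1", "n2", "tip")]), c(90, 60, 30, 0))

  out2 <- bladj_calibrate(tr, c(root = 90, n1 = 45))
  ages2 <- ages_from_lengths(out2)
  expect_equal(unname(ages2[c("root", "n1", "n2")]), c(90, 45, 22.5))
})

test_that("calibration is self-consistent and rejects age conflicts", {
  traits <- load_study_table()
  ages <- load_ages()
  tree <- bladj_calibrate(build_taxonomy_tree(traits, load_backbone()), ages)

  # ultrametric to near machine precision
  depths <- ape::node.depth.edgelength(tree)
  tip_depths <- depths[seq_along(tree$tip.label)]
  expect_lt(max(tip_depths) - min(tip_depths), 1e-9 * max(depths))

  # recomputing node ages from branch lengths reproduces the input ages
  got <- ages_from_lengths(tree)
  for (nm in intersect(names(ages), names(got)))
    expect_equal(unname(got[nm]), unname(ages[[nm]]), tolerance = 1e-9)

  # a child older than its parent is a calibration conflict
  bad <- ages
  bad[["magnoliids"]] <- 150  # older than the 137 Ma root
  expect_error(bladj_calibrate(build_taxonomy_tree(traits, load_backbone()),
                               bad),
               "conflict")
  expect_error(bladj_calibrate(chain_tree(), c(n1 = 10)), "root")
})

test_that("polytomy resolution is seeded, binary, and covariance-neutral", {
  tree <- bladj_calibrate(build_taxonomy_tree(load_study_table(),
                                              load_backbone()),
                          load_ages())
  expect_false(ape::is.binary.phylo(tree))
  r1 <- resolve_polytomies(tree, seed = 7)
  r2 <- resolve_polytomies(tree, seed = 7)
  expect_true(ape::is.binary.phylo(r1))
  expect_equal(ape::write.tree(r1), ape::write.tree(r2))

  # zero-length insertions leave the covariance matrix unchanged
  C0 <- phylo_covariance(tree)
  C1 <- phylo_covariance(r1)
  expect_equal(C1[rownames(C0), colnames(C0)], C0, tolerance = 1e-12)

  # an already binary tree passes through untouched
  bin <- random_ultra_tree(8, seed = 3)
  expect_identical(resolve_polytomies(bin, seed = 1), bin)
})

test_that("the covariance matrix holds shared root-to-ancestor path lengths", {
  two <- ape::read.tree(text = "(A:3,B:3);")
  expect_equal(unclass(phylo_covariance(two)),
               matrix(c(3, 0, 0, 3), 2, dimnames = list(c("A", "B"),
                                                        c("A", "B"))),
               ignore_attr = FALSE)

  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  C <- phylo_covariance(tr)
  expect_equal(C["A", "B"], 1)
  expect_equal(C["A", "C"], 0)
  expect_equal(C["A", "A"], 2)

  star <- ape::read.tree(text = "(A:4,B:4,C:4,D:4);")
  expect_equal(unname(unclass(phylo_covariance(star))), diag(4) * 4)

  nolen <- ape::read.tree(text = "((A,B),C);")
  expect_error(phylo_covariance(nolen), "branch length")

  # symmetric, PSD, and bounded by the diagonal
  big <- random_ultra_tree(12, seed = 5)
  Cb <- phylo_covariance(big)
  expect_equal(Cb, t(Cb))
  expect_true(all(eigen(Cb, symmetric = TRUE, only.values = TRUE)$values >
                    -1e-10))
  expect_true(all(Cb <= diag(Cb)[row(Cb)] + 1e-12))
})

test_that("the lambda transform scales off-diagonals only and keeps PSD", {
  C <- phylo_covariance(random_ultra_tree(10, seed = 9))
  expect_equal(lambda_transform(C, 1), C)
  expect_equal(lambda_transform(C, 0), diag(diag(C)), ignore_attr = TRUE)
  half <- lambda_transform(C, 0.5)
  expect_equal(diag(half), diag(C))
  expect_equal(half[1, 2], 0.5 * C[1, 2])
  expect_error(lambda_transform(C, -0.1), "\\[0, 1\\]")
  expect_error(lambda_transform(C, 1.1), "\\[0, 1\\]")
  for (seed in 1:5) {
    Cs <- phylo_covariance(random_ultra_tree(8, seed = 20 + seed))
    for (lam in c(0, 0.25, 0.5, 0.75, 1)) {
      ev <- eigen(lambda_transform(Cs, lam), symmetric = TRUE,
                  only.values = TRUE)$values
      expect_gt(min(ev), -1e-10)
    }
  }
})

test_that("newick output is stable under write-read-write", {
  tree <- resolve_polytomies(
    bladj_calibrate(build_taxonomy_tree(load_study_table(), load_backbone()),
                    load_ages()), seed = 1)
  nwk1 <- ape::write.tree(tree)
  nwk2 <- ape::write.tree(ape::read.tree(text = nwk1))
  expect_identical(nwk1, nwk2)
})
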