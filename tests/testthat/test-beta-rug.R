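# Asymmetric Ruggiero phylogenetic dissimilarity and uniqueness.

test_that("pairwise dissimilarity matches the hand-worked 4-tip fixture", {
  tr <- four_tip_tree()
  expect_equal(rug_pair_phylo(tr, c("A", "B"), c("A", "C")), 1 / 3)
  expect_equal(rug_pair_phylo(tr, c("A", "C"), c("A", "B")), 0.5)  # asymmetry
  expect_equal(rug_pair_phylo(tr, c("A", "B"), c("A", "B")), 0)
  expect_equal(rug_pair_phylo(tr, c("A", "B"), c("C", "D")), 1)    # disjoint
})

test_that("dissimilarity is zero for nested communities", {
  set.seed(5)
  for (rep in 1:20) {
    tr <- ape::rtree(sample(4:12, 1))
    other <- random_community(tr$tip.label, min_size = 2)
    focal <- sample(other, sample(seq_along(other), 1))
    expect_equal(rug_pair_phylo(tr, focal, other), 0)
  }
})

test_that("dissimilarity equals the brute-force edge-set oracle exactly", {
  set.seed(23)
  for (rep in 1:60) {
    tr <- ape::rtree(sample(3:12, 1))
    focal <- random_community(tr$tip.label)
    other <- random_community(tr$tip.label)
    got <- rug_pair_phylo(tr, focal, other)
    expect_identical(got, rug_pair_brute(tr, focal, other))
    expect_gte(got, 0); expect_lte(got, 1)
  }
})

test_that("on star trees the phylogenetic index reduces to the taxonomic one", {
  set.seed(31)
  tr <- star_tree(15)
  for (rep in 1:50) {
    focal <- random_community(tr$tip.label)
    other <- random_community(tr$tip.label)
    expect_identical(suppressWarnings(rug_pair_phylo(tr, focal, other)),
                     rug_pair_taxonomic(focal, other))
  }
})

test_that("taxonomic Ruggiero proportion follows its definition", {
  expect_equal(rug_pair_taxonomic(c("A", "B"), c("A", "C")), 0.5)
  expect_equal(rug_pair_taxonomic(c("A"), c("A", "B")), 0)
  expect_equal(rug_pair_taxonomic(c("A", "B"), c("C", "D")), 1)
  expect_error(rug_pair_taxonomic(character(0), "A"), "empty")
})

test_that("rug_matrix assembles focal rows in input order with zero diagonal", {
  tr <- four_tip_tree()
  cm <- four_tip_comm()
  m <- rug_matrix(tr, cm)
  expect_equal(unname(m), rbind(c(0, 1 / 3), c(0.5, 0)))
  expect_identical(rownames(m), c("S1", "S2"))

  same <- rbind(a = c(A = 1, B = 1, C = 0, D = 0),
                b = c(A = 1, B = 1, C = 0, D = 0))
  expect_equal(unname(rug_matrix(tr, same)), matrix(0, 2, 2))

  dup <- cm; rownames(dup) <- c("S1", "S1")
  expect_error(rug_matrix(tr, dup), "duplicate")
})

test_that("rug_matrix agrees with per-pair computation on random landscapes", {
  set.seed(77)
  for (rep in 1:10) {
    land <- random_landscape(sample(4:10, 1), sample(3:6, 1))
    m <- rug_matrix(land$tree, land$comm)
    expect_true(all(m >= 0 & m <= 1))
    expect_true(all(diag(m) == 0))
    i <- sample(nrow(m), 1); j <- sample(setdiff(seq_len(nrow(m)), i), 1)
    expect_equal(m[i, j],
                 rug_pair_phylo(land$tree,
                                community_species_of(land$comm, i),
                                community_species_of(land$comm, j)))
  }
})

test_that("rug_row streams a single focal row identical to the full matrix", {
  land <- random_landscape(8, 5, seed = 9)
  m <- rug_matrix(land$tree, land$comm)
  bi <- branch_incidence(land$tree, land$comm)
  for (s in rownames(land$comm)) {
    expect_equal(rug_row(land$tree, land$comm, s, incidence = bi), m[s, ])
  }
  expect_error(rug_row(land$tree, land$comm, "nope"), "unknown focal site")
})

test_that("uniqueness is the off-diagonal row mean and is column-permutation invariant", {
  m <- rbind(c(0, 1 / 3), c(0.5, 0))
  rownames(m) <- colnames(m) <- c("S1", "S2")
  expect_equal(unname(phylo_uniqueness(m)), c(1 / 3, 0.5))

  z <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_equal(unname(phylo_uniqueness(z)), c(0, 0, 0))

  cst <- matrix(0.4, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(cst) <- 0
  expect_equal(unname(phylo_uniqueness(cst)), rep(0.4, 4))

  land <- random_landscape(8, 6, seed = 3)
  m <- rug_matrix(land$tree, land$comm)
  u1 <- phylo_uniqueness(m)
  # permuting the comparison sites of any focal row leaves its mean unchanged
  for (i in seq_len(nrow(m))) {
    perm <- sample(setdiff(seq_len(nrow(m)), i))
    expect_equal(mean(m[i, perm]) * length(perm) / (nrow(m) - 1), u1[[i]])
  }
  expect_error(phylo_uniqueness(matrix(0, 1, 1)), "at least 2")
})

test_that("a focal community of only zero-length branches is rejected", {
  tr <- four_tip_tree()
  tr$edge.length[c(1, 2, 3)] <- 0  # AB stem, A, B
  expect_error(rug_pair_phylo(tr, c("A", "B"), c("C", "D")),
               "zero total branch length")
})
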