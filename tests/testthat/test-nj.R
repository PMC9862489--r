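test_that("three taxa solve the three-point formulas exactly", {
  lab <- c("a", "b", "c")
  D <- matrix(c(0, 3, 5,
                3, 0, 6,
                5, 6, 0), 3, dimnames = list(lab, lab))
  phy <- nj_tree(D)
  coph <- ape::cophenetic.phylo(phy)[lab, lab]
  expect_equal(coph, D, tolerance = 1e-12)
  # branch of 'a': (d_ab + d_ac - d_bc)/2 = 1
  a_edge <- phy$edge.length[phy$edge[, 2] == match("a", phy$tip.label)]
  expect_equal(a_edge, 1)
})

test_that("NJ is exact on additive matrices and beats no other topology", {
  d4 <- additive_matrix("((a:1,b:2):1.5,(c:0.7,d:2.2):0.8);")
  phy <- nj_tree(d4)
  expect_equal(ape::cophenetic.phylo(phy)[rownames(d4), colnames(d4)], d4,
               tolerance = 1e-12)
  ora <- best_ls_topology(d4)
  expect_equal(ape::dist.topo(ape::unroot(phy), ape::unroot(ora$tree)), 0,
               ignore_attr = TRUE)
  # the true topology fits with ~0 RSS, the other two do not
  expect_lt(min(ora$all_rss), 1e-20)
  expect_gt(sort(ora$all_rss)[2], 1e-4)

  d5 <- additive_matrix("(((a:1,b:0.5):0.6,c:1.2):0.4,(d:0.9,e:1.1):0.3);")
  phy5 <- nj_tree(d5)
  expect_equal(ape::cophenetic.phylo(phy5)[rownames(d5), colnames(d5)], d5,
               tolerance = 1e-12)
  ora5 <- best_ls_topology(d5)
  expect_equal(ape::dist.topo(ape::unroot(phy5), ape::unroot(ora5$tree)), 0,
               ignore_attr = TRUE)
})

test_that("NJ agrees with an independent implementation on random input", {
  set.seed(91)
  for (rep in 1:5) {
    n <- sample(5:8, 1)
    pts <- matrix(runif(n * 3), n)
    D <- as.matrix(dist(pts))
    dimnames(D) <- list(paste0("t", 1:n), paste0("t", 1:n))
    mine <- nj_tree(D)
    theirs <- ape::nj(D)
    expect_equal(ape::dist.topo(ape::unroot(mine), ape::unroot(theirs)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("degenerate and invalid matrices are handled", {
  Z <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  star <- nj_tree(Z)
  expect_true(all(star$edge.length < 1e-12))
  bad <- Z; bad[1, 2] <- 1
  expect_error(nj_tree(bad), "symmetric")
  expect_error(nj_tree(Z[1:2, 1:2]), "at least 3")
  # negative branch lengths are clamped, never emitted
  D <- matrix(c(0, 1, 1, 1,
                1, 0, 1, 1,
                1, 1, 0, 1.99,
                1, 1, 1.99, 0), 4,
              dimnames = list(letters[1:4], letters[1:4]))
  expect_true(all(nj_tree(D)$edge.length >= 0))
})

test_that("bootstrap supports behave at the granularity limits", {
  set.seed(92)
  base <- random_dna(400)
  far <- mutate_sites(base, n_ts = 14, n_tv = 6)  # ~5%
  seqs <- tibble::tibble(
    id = c(paste0("a", 1:4), paste0("b", 1:4)),
    species = rep(c("A", "B"), each = 4),
    sequence = c(rep(base, 4), rep(far, 4)))
  one <- bootstrap_nj(seqs, n_boot = 1, seed = 93)
  sup <- as.numeric(one$node.label)
  expect_true(all(sup[!is.na(sup)] %in% c(0, 100)))

  many <- bootstrap_nj(seqs, n_boot = 100, seed = 94)
  # the cluster bipartition (A vs B) is recovered with ~100% support:
  # prop.part lists clades in the same internal-node order as node.label
  parts <- ape::prop.part(many)
  labs <- attr(parts, "labels")
  clade_sets <- lapply(parts, function(p) sort(labs[p]))
  sup <- as.numeric(many$node.label)
  cluster_nodes <- which(vapply(clade_sets, function(s) {
    identical(s, sort(paste0("a", 1:4))) || identical(s, sort(paste0("b", 1:4)))
  }, logical(1)))
  expect_gte(length(cluster_nodes), 1)
  expect_true(all(sup[cluster_nodes] >= 99))
})
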