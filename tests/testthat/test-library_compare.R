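# incidence fixture: A = OTUs 1..6, B = 4..9, C = 8..12
abc_table <- local({
  counts <- matrix(0L, 12, 3, dimnames = list(NULL, c("A", "B", "C")))
  counts[1:6, "A"] <- 1L
  counts[4:9, "B"] <- 1L
  counts[8:12, "C"] <- 1L
  make_otu_table(counts)
})

test_that("observed Venn regions match direct set arithmetic", {
  vp <- venn_partition(abc_table, c("A", "B", "C"))
  expect_equal(vp$regions[["A"]], 3)       # {1,2,3}
  expect_equal(vp$regions[["B"]], 1)       # {7}
  expect_equal(vp$regions[["C"]], 3)       # {10,11,12}
  expect_equal(vp$regions[["A&B"]], 3)     # {4,5,6}
  expect_equal(vp$regions[["B&C"]], 2)     # {8,9}
  expect_equal(vp$regions[["A&C"]], 0)
  expect_equal(vp$regions[["A&B&C"]], 0)

  # inclusion-exclusion closure: regions containing L sum to richness of L
  inc <- otu_incidence(abc_table)
  for (l in c("A", "B", "C")) {
    in_l <- grepl(l, names(vp$regions))
    expect_equal(sum(vp$regions[in_l]), sum(inc[, l]))
  }
})

test_that("two-library Venn handles disjoint and identical incidence", {
  disj <- make_otu_table(cbind(A = c(1, 1, 1, 0, 0), B = c(0, 0, 0, 1, 1)))
  vp <- venn_partition(disj, c("A", "B"))
  expect_equal(unname(vp$regions[c("A", "B", "A&B")]), c(3, 2, 0))

  same <- make_otu_table(cbind(A = c(2, 1, 5), B = c(1, 3, 2)))
  vp2 <- venn_partition(same, c("A", "B"))
  expect_equal(unname(vp2$regions[c("A", "B", "A&B")]), c(0, 0, 3))

  expect_error(venn_partition(make_otu_table(cbind(A = 1, B = 1, C = 1,
                                                   D = 1))),
               "2 or 3")
})

test_that("chao-shared Venn floors at observed regions", {
  counts <- cbind(A = c(1, 1, 2, 3, 0, 0), B = c(1, 0, 2, 0, 1, 4))
  tab <- make_otu_table(counts)
  vp <- venn_partition(tab, c("A", "B"), mode = "chao_shared")
  obs <- venn_partition(tab, c("A", "B"), mode = "observed")
  expect_true(all(vp$regions >= obs$regions - 1e-9))
  # per-library reconstruction is at least the observed richness
  expect_gte(vp$regions[["A"]] + vp$regions[["A&B"]], 4)
})

test_that("richness gain reports both conventions", {
  # richest 10 OTUs; B adds {11,12}, C adds {13}; all novel, disjoint
  counts <- matrix(0L, 13, 3, dimnames = list(NULL, c("R", "B", "C")))
  counts[1:10, "R"] <- 1L
  counts[11:12, "B"] <- 1L
  counts[13, "C"] <- 1L
  g <- richness_gain(make_otu_table(counts))
  expect_equal(g$richest, "R")
  expect_equal(g$hR, 10)
  expect_equal(g$gain_pct_union, 30)
  expect_equal(g$gain_pct_sum, 30)

  # overlapping novel phylotypes make the conventions diverge
  counts2 <- matrix(0L, 12, 3, dimnames = list(NULL, c("R", "B", "C")))
  counts2[1:10, "R"] <- 1L
  counts2[11:12, "B"] <- 1L
  counts2[12, "C"] <- 1L
  g2 <- richness_gain(make_otu_table(counts2))
  expect_equal(g2$gain_pct_union, 20)
  expect_equal(g2$gain_pct_sum, 30)

  # identical libraries gain nothing
  same <- make_otu_table(cbind(A = c(1, 1, 1), B = c(2, 1, 5)))
  expect_equal(richness_gain(same)$gain_pct_union, 0)
  expect_error(richness_gain(make_otu_table(cbind(A = c(1, 1)))),
               "at least 2")
})

test_that("gain is zero exactly when the richest library contains everything", {
  set.seed(15)
  for (trial in 1:20) {
    counts <- matrix(rbinom(30, 1, 0.5), 10, 3,
                     dimnames = list(NULL, c("A", "B", "C")))
    counts[rowSums(counts) == 0, 1] <- 1L
    g <- richness_gain(make_otu_table(counts))
    inc <- counts > 0
    others_in_richest <- all(inc[rowSums(inc[, setdiff(colnames(inc),
                                                        g$richest)]) > 0,
                                 g$richest])
    expect_equal(g$gain_pct_union == 0, others_in_richest)
  }
})

test_that("jaccard dissimilarity equals one minus shared over union", {
  same <- make_otu_table(cbind(A = c(1, 2, 3), B = c(3, 2, 1)))
  expect_equal(jaccard_dissimilarity(same)["A", "B"], 0)

  disj <- make_otu_table(cbind(A = c(1, 1, 0, 0), B = c(0, 0, 1, 1)))
  expect_equal(jaccard_dissimilarity(disj)["A", "B"], 1)

  # A = {1,2,3,4}, B = {3,4,5,6}: 1 - 2/6
  part <- make_otu_table(cbind(A = c(1, 1, 1, 1, 0, 0),
                               B = c(0, 0, 1, 1, 1, 1)))
  expect_equal(jaccard_dissimilarity(part)["A", "B"], 1 - 2 / 6)

  empty <- make_otu_table(cbind(A = c(1, 1), B = c(0, 0)))
  expect_warning(de <- jaccard_dissimilarity(empty), "zero OTUs")
  expect_equal(de["A", "B"], 1)
})

test_that("jaccard agrees with vegan and satisfies the triangle inequality", {
  skip_if_not_installed("vegan")
  set.seed(16)
  for (trial in 1:10) {
    counts <- matrix(rbinom(40, 1, 0.5), 10, 4,
                     dimnames = list(NULL, paste0("L", 1:4)))
    counts[rowSums(counts) == 0, 1] <- 1L
    tab <- make_otu_table(counts)
    d <- jaccard_dissimilarity(tab)
    vd <- as.matrix(vegan::vegdist(t(counts), method = "jaccard",
                                   binary = TRUE))
    expect_equal(unname(d), unname(vd), tolerance = 1e-12)
    for (i in 1:4) for (j in 1:4) for (k in 1:4)
      expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
  }
})

test_that("upgma recovers ultrametric input and matches the naive oracle", {
  # two items: single merge at their distance
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("a", "b"),
                                                     c("a", "b")))
  hc2 <- upgma(d2)
  expect_equal(hc2$height, 0.4)

  # ultrametric 4x4: cophenetic distances reproduce the input exactly
  ids <- c("w", "x", "y", "z")
  du <- matrix(0.8, 4, 4, dimnames = list(ids, ids))
  du[1, 2] <- du[2, 1] <- 0.2
  du[3, 4] <- du[4, 3] <- 0.4
  diag(du) <- 0
  expect_equal(as.matrix(stats::cophenetic(upgma(du)))[ids, ids], du)

  # random 6x6: cophenetic equals the naive O(n^3) UPGMA oracle
  set.seed(17)
  x <- matrix(rnorm(6 * 3), 6)
  d6 <- as.matrix(dist(x))
  rownames(d6) <- colnames(d6) <- paste0("t", 1:6)
  expect_equal(as.matrix(stats::cophenetic(upgma(d6))),
               oracle_upgma_cophenetic(d6)[labels(stats::cophenetic(upgma(d6))),
                                           labels(stats::cophenetic(upgma(d6)))])
  expect_error(upgma(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("upgma merge heights are monotone", {
  set.seed(18)
  for (trial in 1:5) {
    x <- matrix(rnorm(8 * 3), 8)
    d <- as.matrix(dist(x))
    rownames(d) <- colnames(d) <- paste0("t", 1:8)
    expect_true(all(diff(upgma(d)$height) >= -1e-12))
  }
})

test_that("neighbor joining recovers additive distances exactly", {
  # build an additive matrix from a known random tree
  set.seed(19)
  ref <- ape::rtree(6)
  ref$edge.length <- runif(nrow(ref$edge), 0.1, 1)
  d <- ape::cophenetic.phylo(ref)
  nj <- nj_tree(d)
  expect_equal(ape::cophenetic.phylo(nj)[rownames(d), colnames(d)], d,
               tolerance = 1e-8)
  expect_true(all(nj$edge.length >= 0))

  # 3 items: closed-form star resolution
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  star <- nj_tree(d3)
  coph <- ape::cophenetic.phylo(star)
  expect_equal(coph["a", "b"], 3)
  expect_equal(coph["a", "c"], 4)
  expect_equal(coph["b", "c"], 5)
  expect_error(nj_tree(d2 <- matrix(0, 2, 2)), "at least 3")
})

test_that("negative NJ branches are clamped with sister transfer", {
  # non-additive matrix known to induce a negative NJ branch
  d <- matrix(c(0, 5, 9, 9, 5, 0, 10, 10, 9, 10, 0, 1, 9, 10, 1, 0), 4,
              dimnames = list(letters[1:4], letters[1:4]))
  d["a", "b"] <- d["b", "a"] <- 0.1  # distort
  tree <- nj_tree(d)
  expect_true(all(tree$edge.length >= 0))
})

test_that("unifrac distance matches the edge-walking oracle", {
  set.seed(20)
  for (trial in 1:5) {
    tree <- ape::rcoal(16)
    tree$edge.length <- rexp(nrow(tree$edge))
    labels <- stats::setNames(sample(c("A", "B"), 16, replace = TRUE),
                              tree$tip.label)
    labels[1:2] <- c("A", "B")  # both communities present
    got <- unifrac_unweighted(tree, labels, pair = c("A", "B"),
                              permutations = 0)
    expect_equal(got$distance, oracle_unifrac(tree, labels, "A", "B"))
  }
})

test_that("unifrac agrees with picante on shared tip sets", {
  skip_if_not_installed("picante")
  set.seed(21)
  tree <- ape::rcoal(20)
  labels <- stats::setNames(rep(c("A", "B"), 10), tree$tip.label)
  comm <- rbind(A = as.integer(labels == "A"), B = as.integer(labels == "B"))
  colnames(comm) <- tree$tip.label
  pic <- picante::unifrac(comm, tree)
  got <- unifrac_unweighted(tree, labels, permutations = 0)
  expect_equal(got$distance, as.numeric(pic), tolerance = 1e-10)
})

test_that("unifrac limiting cases and scale invariance hold", {
  tree <- ape::rcoal(8)
  # identical leaf sets cannot be compared as two disjoint communities,
  # but interleaving every clade pair symmetrically gives distance 0 on a
  # two-leaf cherry comparison; use duplicated labels on a 2-community
  # balanced tree instead
  ids <- tree$tip.label
  # disjoint subtrees: communities split at the root -> distance 1
  root_kids <- tree$edge[tree$edge[, 1] == 9, 2]
  et_labels <- stats::setNames(rep("B", 8), ids)
  clade <- if (root_kids[1] <= 8) ids[root_kids[1]] else
    ape::extract.clade(tree, root_kids[1])$tip.label
  et_labels[clade] <- "A"
  res <- unifrac_unweighted(tree, et_labels, permutations = 0)
  expect_equal(res$distance, 1)

  # rescaling branch lengths leaves the distance unchanged
  labels <- stats::setNames(rep(c("A", "B"), 4), ids)
  d1 <- unifrac_unweighted(tree, labels, permutations = 0)$distance
  tree2 <- tree
  tree2$edge.length <- tree$edge.length * 37.5
  expect_equal(unifrac_unweighted(tree2, labels, permutations = 0)$distance,
               d1)

  expect_error(unifrac_unweighted(tree, labels[1:4], permutations = 0),
               "unlabeled")
  expect_error(unifrac_unweighted(tree, labels, pair = c("A", "Z"),
                                  permutations = 0), "zero leaves")
})

test_that("permutation p-values are valid and super-uniform under the null", {
  # p bounded below by 1/(perms+1), Bonferroni capped at 1
  spec <- synthetic_spec(seed = 31, tree_regime = "interleaved")
  lt <- gen_labeled_tree(spec)
  res <- unifrac_unweighted(lt$tree, lt$communities, permutations = 50,
                            seed = 1)
  expect_gte(res$p_value, 1 / 51)
  expect_lte(res$p_bonferroni, 1)

  # calibration: under label exchange the p-value is super-uniform
  set.seed(77)
  pvals <- vapply(1:60, function(i) {
    lt <- gen_labeled_tree(synthetic_spec(seed = 1000 + i,
                                          tree_regime = "interleaved",
                                          n_leaves = 12))
    unifrac_unweighted(lt$tree, lt$communities, permutations = 60,
                       seed = i)$p_value
  }, numeric(1))
  expect_lte(mean(pvals <= 0.05), 0.15)
  expect_lte(mean(pvals <= 0.25), 0.45)
})
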