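test_that("PCA reproduces the closed-form 2x2 eigenstructure", {
  # two sites whose sample covariance is computable in closed form
  calls <- matrix(c(0L, 0L, 2L, 2L, 0L, 2L,
                    0L, 2L, 0L, 2L, 0L, 2L), 6, 2)
  gm <- make_gm(calls)
  res <- pca_genotypes(gm)
  S <- stats::cov(calls)
  tr <- S[1, 1] + S[2, 2]
  det_ <- S[1, 1] * S[2, 2] - S[1, 2]^2
  ev_expected <- sort(c((tr + sqrt(tr^2 - 4 * det_)) / 2,
                        (tr - sqrt(tr^2 - 4 * det_)) / 2),
                      decreasing = TRUE)
  expect_equal(res$eigenvalues, ev_expected, tolerance = 1e-12)
  expect_equal(sum(res$pct_var), 100, tolerance = 1e-6)
  expect_true(all(diff(res$eigenvalues) <= 1e-12))
})

test_that("PC1 aligns with the shared axis of two duplicated sites", {
  calls <- matrix(rep(c(0L, 0L, 2L, 2L), 2), 4, 2)
  gm <- make_gm(calls)
  res <- pca_genotypes(gm)
  expect_equal(res$eigenvalues[2], 0, tolerance = 1e-12)
  # loadings proportional to (1,1)/sqrt(2): scores of (0,0) vs (2,2) rows
  # differ only along PC1
  expect_equal(abs(diff(range(res$scores[, 1]))), 2 * sqrt(2),
               tolerance = 1e-10)
})

test_that("a constant matrix is flagged degenerate", {
  gm <- make_gm(matrix(0L, 4, 3))
  res <- pca_genotypes(gm)
  expect_true(res$degenerate)
  expect_true(all(is.na(res$pct_var)))
})

test_that("the first two PCs separate three diverged groups", {
  skip_if_not_installed("cluster")
  panel <- simulate_panel(sim_config(n_chrom = 4, sites_per_chrom = 250,
                                     lines_per_group = 20, seed = 37,
                                     miss_rate_mean = 0, miss_rate_sd = 0,
                                     ref_bias_weight = 0, het_rate = 0,
                                     tertiary_rate = 0))
  res <- pca_genotypes(panel$truth$complete)
  lab <- as.integer(factor(panel$truth$group_label[rownames(res$scores)]))
  sil <- cluster::silhouette(lab, stats::dist(res$scores[, 1:2]))
  expect_gt(mean(sil[, "sil_width"]), 0.5)
})

test_that("Nei distance matches hand-worked and brute-force values", {
  gm <- make_gm(rbind(X = c(0L, 2L), Y = c(0L, 2L)))
  expect_equal(unname(nei_distance(gm)["X", "Y"]), 0)

  # two inbreds differing at exactly 1 of 2 loci -> D = -ln(0.5)
  gm <- make_gm(rbind(X = c(0L, 0L), Y = c(0L, 2L)))
  expect_equal(unname(nei_distance(gm)["X", "Y"]), -log(0.5))

  set.seed(55)
  for (i in 1:20) {
    calls <- matrix(2L * rbinom(5 * 20, 1, 0.5), 5, 20)
    rownames(calls) <- paste0("L", 1:5)
    gm <- make_gm(calls)
    d <- nei_distance(gm)
    expect_equal(unname(d["L1", "L3"]), nei_oracle(calls[1, ], calls[3, ]),
                 tolerance = 1e-12)
    expect_true(isSymmetric(unclass(d)))
    perm <- sample(20)
    gm_p <- make_gm(calls[, perm], pos = perm * 100L)
    expect_equal(unclass(nei_distance(gm_p)), unclass(d), tolerance = 1e-12)
  }
})

test_that("Nei distance is invariant to duplicating every locus", {
  set.seed(66)
  calls <- matrix(2L * rbinom(4 * 15, 1, 0.5), 4, 15)
  rownames(calls) <- paste0("L", 1:4)
  gm <- make_gm(calls)
  dup <- make_gm(cbind(calls, calls), pos = seq_len(30) * 10L)
  expect_equal(unclass(nei_distance(dup)), unclass(nei_distance(gm)),
               tolerance = 1e-12)

  # pair sharing no allele anywhere -> infinite, flagged
  opp <- make_gm(rbind(X = c(0L, 0L), Y = c(2L, 2L)))
  d <- nei_distance(opp)
  expect_true(is.infinite(d["X", "Y"]))
  expect_equal(nrow(attr(d, "infinite_pairs")), 1)
})

test_that("Ward clustering matches a hand-run Lance-Williams trace", {
  d <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  d["A", "C"] <- d["C", "A"] <- 5
  d["B", "C"] <- d["C", "B"] <- 5
  tree <- ward_cluster(d)
  expect_equal(tree$height[1], 0)
  expect_setequal(tree$labels[-tree$merge[1, ]], c("A", "B"))

  # 4 leaves, hand trace: merge (A,B) at 1; (C,D) at 2; root at 18.5
  d4 <- matrix(10, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(d4) <- 0
  d4["A", "B"] <- d4["B", "A"] <- 1
  d4["C", "D"] <- d4["D", "C"] <- 2
  tree <- ward_cluster(d4)
  expect_equal(tree$height, c(1, 2, 18.5))

  expect_error(ward_cluster(matrix(0, 1, 1)), "at least 2")
  dinf <- d4; dinf["A", "C"] <- dinf["C", "A"] <- Inf
  expect_error(ward_cluster(dinf), "finite")
})

test_that("Ward merge heights equal a naive O(n^3) re-scan oracle", {
  set.seed(88)
  for (i in 1:20) {
    n <- sample(5:8, 1)
    x <- matrix(rnorm(n * 4), n)
    D <- as.matrix(dist(x))
    dimnames(D) <- list(paste0("L", 1:n), paste0("L", 1:n))
    tree <- ward_cluster(D)
    expect_equal(tree$height, ward_oracle_heights(D), tolerance = 1e-9)
  }
})

test_that("cutting the tree recovers planted blocks and honors k bounds", {
  set.seed(12)
  # two well-separated blocks
  x <- rbind(matrix(rnorm(10 * 2), 10), matrix(rnorm(8 * 2, mean = 50), 8))
  D <- as.matrix(dist(x))
  dimnames(D) <- list(paste0("L", 1:18), paste0("L", 1:18))
  tree <- ward_cluster(D)
  g <- cut_tree(tree, 2)
  expect_equal(length(unique(g[1:10])), 1)
  expect_equal(length(unique(g[11:18])), 1)
  expect_false(g[1] == g[11])

  expect_equal(unname(cut_tree(tree, 1)), rep(1L, 18))
  expect_equal(length(unique(cut_tree(tree, 18))), 18)
  expect_error(cut_tree(tree, 0), "k")
  expect_error(cut_tree(tree, 19), "k")
})

test_that("nested subgroups are recovered at a deeper cut", {
  skip_if_not_installed("mclust")
  # 3 groups x 15 lines with strong within-group founder structure gives
  # recoverable subgroups below the main split
  panel <- simulate_panel(sim_config(n_chrom = 4, sites_per_chrom = 300,
                                     lines_per_group = 15,
                                     n_founders_per_group = 2,
                                     recycle_generations = 1, seed = 57,
                                     miss_rate_mean = 0, miss_rate_sd = 0,
                                     ref_bias_weight = 0, het_rate = 0,
                                     tertiary_rate = 0))
  dm <- nei_distance(panel$truth$complete)
  tree <- ward_cluster(dm)
  g3 <- cut_tree(tree, 3)
  ari <- mclust::adjustedRandIndex(
    g3, panel$truth$group_label[names(g3)])
  expect_equal(ari, 1.0)
})

test_that("Newick export is exact for two leaves and round-trips heights", {
  tree <- list(merge = matrix(c(-1L, -2L), 1), height = 0.5,
               labels = c("A", "B"), order = 1:2)
  class(tree) <- "hclust"
  expect_equal(to_newick(tree), "(A:0.5,B:0.5);")

  set.seed(91)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    x <- matrix(rnorm(n * 3), n)
    D <- as.matrix(dist(x))
    dimnames(D) <- list(paste0("L", 1:n), paste0("L", 1:n))
    ward <- ward_cluster(D)
    phy <- ape::read.tree(text = to_newick(ward))
    expect_setequal(phy$tip.label, ward$labels)
    coph_ours <- as.matrix(stats::cophenetic(ward))
    coph_phy <- ape::cophenetic.phylo(phy) / 2
    expect_equal(coph_phy[rownames(coph_ours), colnames(coph_ours)],
                 coph_ours, tolerance = 1e-6)
  }
})

test_that("leaf names needing quoting are quoted", {
  tree <- list(merge = matrix(c(-1L, -2L), 1), height = 1,
               labels = c("B 73", "Mo17"), order = 1:2)
  class(tree) <- "hclust"
  nwk <- to_newick(tree)
  expect_match(nwk, "'B 73'", fixed = TRUE)
  phy <- ape::read.tree(text = nwk)
  expect_setequal(gsub("^'|'$", "", phy$tip.label), c("B 73", "Mo17"))
})
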