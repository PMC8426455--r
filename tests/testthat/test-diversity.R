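test_that("alpha diversity matches closed forms", {
  tab <- matrix(c(5, 5, 5, 5,
                  10, 0, 0, 0), 4, 2,
                dimnames = list(c("A", "B", "C", "D"), c("even", "single")))
  sh <- alpha_diversity(tab, "shannon")
  expect_equal(unname(sh), c(2, 0))
  expect_equal(unname(alpha_diversity(tab, "observed_features")), c(4, 1))
  expect_error(alpha_diversity(cbind(tab, empty = c(0, 0, 0, 0)), "shannon"),
               "empty")
  # Shannon is maximal (log2 S) only at the uniform profile
  set.seed(1)
  p <- rmultinom(1, 500, c(0.5, 0.3, 0.1, 0.1))
  dimnames(p) <- list(c("A", "B", "C", "D"), "x")
  expect_lt(alpha_diversity(p, "shannon"), 2)
})

test_that("Faith's PD includes the root path", {
  tr <- ape::read.tree(text = "(A:1,B:1);")
  tab <- matrix(c(3, 5), 2, 1, dimnames = list(c("A", "B"), "s"))
  expect_equal(unname(alpha_diversity(tab, "faith_pd", tree = tr)), 2)
  # single-taxon community: branch back to the root
  tr2 <- tree3()
  tab2 <- matrix(c(0, 0, 4), 3, 1, dimnames = list(c("A", "B", "C"), "s"))
  expect_equal(unname(alpha_diversity(tab2, "faith_pd", tree = tr2)), 2)
})

test_that("beta diversity hits its boundary cases", {
  tab <- matrix(c(4, 6, 4, 6, 0, 9), 2, 3,
                dimnames = list(c("A", "B"), c("s1", "s2", "s3")))
  d <- beta_diversity(tab, "bray_curtis")
  expect_symmetric(d)
  expect_equal(d["s1", "s2"], 0)
  disj <- matrix(c(5, 0, 0, 7), 2, 2, dimnames = list(c("A", "B"), c("x", "y")))
  expect_equal(beta_diversity(disj, "bray_curtis")["x", "y"], 1)

  tr <- ape::read.tree(text = "(A:1,B:1);")
  expect_equal(beta_diversity(disj, "weighted_unifrac", tr)["x", "y"], 1)
  expect_equal(beta_diversity(tab[, 1:2], "weighted_unifrac", tr)["s1", "s2"], 0)
  expect_error(beta_diversity(tab, "weighted_unifrac"), "tree")
})

test_that("weighted UniFrac on a star tree is a weighted L1 distance", {
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  tab <- random_table(4, 3, seed = 5)
  rownames(tab) <- c("A", "B", "C", "D")
  rel <- sweep(tab, 2, colSums(tab), "/")
  d <- beta_diversity(tab, "weighted_unifrac", star)
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(d[i, j],
                 sum(abs(rel[, i] - rel[, j])) / sum(rel[, i] + rel[, j]),
                 tolerance = 1e-12)
  }
})

test_that("weighted UniFrac agrees with phyloseq", {
  skip_if_not_installed("phyloseq")
  tr <- simulate_tree(25, seed = 6)
  tab <- random_table(25, 4, seed = 7)
  rownames(tab) <- tr$tip.label
  mine <- beta_diversity(tab, "weighted_unifrac", tr)
  ps <- phyloseq::phyloseq(phyloseq::otu_table(tab, taxa_are_rows = TRUE), tr)
  ref <- as.matrix(phyloseq::UniFrac(ps, weighted = TRUE, normalized = TRUE))
  expect_equal(mine, ref[rownames(mine), colnames(mine)], tolerance = 1e-8)
})

test_that("PCoA recovers geometry and reports eigenvalues faithfully", {
  # three equidistant points: two equal positive eigenvalues
  d3 <- matrix(1, 3, 3) - diag(3)
  dimnames(d3) <- list(letters[1:3], letters[1:3])
  p3 <- pcoa(d3, k = 2)
  eig <- p3$eigenvalues
  expect_equal(eig[1], eig[2], tolerance = 1e-9)
  expect_lt(abs(eig[3]), 1e-9)

  # Euclidean distances from known 2-D coordinates are reproduced exactly
  set.seed(8)
  X <- matrix(rnorm(20), 10, 2)
  dX <- as.matrix(dist(X))
  dimnames(dX) <- list(paste0("s", 1:10), paste0("s", 1:10))
  rec <- pcoa(dX, k = 2)$coordinates
  proc <- vegan::procrustes(X, rec)
  expect_lt(sum(proc$resid^2), 1e-12)

  expect_error(pcoa(d3, k = 3), "k must be")
  z <- pcoa(matrix(0, 4, 4, dimnames = list(1:4, 1:4)), k = 2)
  expect_true(all(abs(z$eigenvalues) < 1e-12))
})

test_that("PCoA eigenvalue sum equals the trace of the centered matrix", {
  set.seed(9)
  tab <- random_table(15, 8, seed = 9)
  dm <- beta_diversity(tab, "bray_curtis")
  res <- pcoa(dm, k = 3)
  A <- -0.5 * dm^2
  J <- diag(8) - matrix(1 / 8, 8, 8)
  expect_equal(sum(res$eigenvalues), sum(diag(J %*% A %*% J)), tolerance = 1e-8)
})

test_that("PERMANOVA separates clusters and is seed-stable", {
  set.seed(10)
  a <- matrix(rpois(20 * 5, 5), 20, 5)
  b <- matrix(rpois(20 * 5, 5), 20, 5) + 40
  tab <- cbind(a, b)
  dimnames(tab) <- list(paste0("t", 1:20), paste0("s", 1:10))
  dm <- beta_diversity(tab, "bray_curtis")
  g <- rep(c("a", "b"), each = 5)
  fit <- permanova(dm, g, n_perm = 199, seed = 3)
  # minimum attainable p up to the group-swap permutation, which gives a tied F
  expect_lte(fit$p, 2 / 200)
  expect_identical(fit, permanova(dm, g, n_perm = 199, seed = 3))
  expect_error(permanova(dm, c("a", rep("b", 9)), 99), ">= 2 samples")
  pw <- pairwise_permanova(dm, g, n_perm = 99, seed = 4)
  expect_equal(nrow(pw), 1)
})

test_that("Kruskal-Wallis matches hand rank arithmetic and handles ties", {
  res <- compare_groups(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(res$H, 3.857, tolerance = 1e-3)
  expect_equal(compare_groups(rep(2, 6), rep(c("a", "b"), 3)),
               list(H = 0, p = 1))
  # invariant to a joint permutation of (value, group) pairs
  set.seed(11)
  x <- rnorm(12); g <- rep(letters[1:3], 4); o <- sample(12)
  expect_equal(compare_groups(x, g)$H, compare_groups(x[o], g[o])$H)
  expect_error(compare_groups(x, rep("a", 12)), "groups")
})
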