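test_that("patristic distances match hand sums and a path-walking oracle", {
  d <- patristic_distances(tree3())
  expect_equal(d["A", "B"], 2)
  expect_equal(d["A", "C"], 4)
  expect_equal(d["B", "C"], 4)
  for (sd in 1:5) {
    tr <- simulate_tree(12, seed = sd + 40)
    d <- patristic_distances(tr)
    # oracle: sum edge lengths along the node path for random tip pairs
    el <- tr$edge.length
    key <- paste(tr$edge[, 1], tr$edge[, 2])
    for (k in 1:5) {
      ij <- sample(12, 2)
      path <- ape::nodepath(tr, ij[1], ij[2])
      steps <- cbind(path[-length(path)], path[-1])
      len <- sum(el[match(paste(pmin(steps[, 1], steps[, 2]),
                                pmax(steps[, 1], steps[, 2])),
                          paste(pmin(tr$edge[, 1], tr$edge[, 2]),
                                pmax(tr$edge[, 1], tr$edge[, 2])))])
      expect_equal(d[ij[1], ij[2]], len, tolerance = 1e-12)
    }
    expect_true(all(d <= 2 + 1e-9))  # ultrametric depth-1 bound
  }
})

test_that("MPD and MNTD match hand arithmetic and picante", {
  d <- patristic_distances(tree3())
  ab <- mpd_mntd(c("A", "B"), d)
  expect_equal(ab$mpd, 2)
  expect_equal(ab$mntd, 2)
  abc <- mpd_mntd(c("A", "B", "C"), d)
  expect_equal(abc$mpd, 10 / 3)
  expect_equal(abc$mntd, 8 / 3)
  expect_true(mpd_mntd("A", d)$undefined)
  # equal abundance weights reduce to the unweighted statistics (MNTD)
  w <- mpd_mntd(c("A", "B", "C"), d, abundances = c(A = 2, B = 2, C = 2))
  expect_equal(w$mntd, abc$mntd)

  tr <- simulate_tree(20, seed = 51)
  tab <- random_table(20, 6, lambda = 2, seed = 52)
  rownames(tab) <- tr$tip.label
  dc <- patristic_distances(tr)
  comm <- t(tab)
  expect_equal(
    vapply(colnames(tab), function(s)
      mpd_mntd(rownames(tab)[tab[, s] > 0], dc)$mntd, numeric(1)),
    stats::setNames(picante::mntd(comm, dc), colnames(tab)),
    tolerance = 1e-12)
  expect_equal(
    vapply(colnames(tab), function(s)
      mpd_mntd(rownames(tab)[tab[, s] > 0], dc)$mpd, numeric(1)),
    stats::setNames(picante::mpd(comm, dc), colnames(tab)),
    tolerance = 1e-12)
})

test_that("exhaustive SES reproduces the enumerated null exactly", {
  d <- patristic_distances(tree3())
  tab <- matrix(c(1, 1, 0), 3, 1, dimnames = list(c("A", "B", "C"), "s1"))
  res <- ses_phylo(tab, d, "mntd", pool = c("A", "B", "C"), exhaustive = TRUE)
  # null MNTDs over the 3 equiprobable pairs: 2, 4, 4
  expect_equal(res$null_mean, 10 / 3)
  expect_equal(res$null_sd, stats::sd(c(2, 4, 4)))
  expect_equal(res$ses, (2 - 10 / 3) / stats::sd(c(2, 4, 4)), tolerance = 1e-9)
  expect_equal(res$nti, -res$ses)

  # SES is invariant to a uniform rescaling of branch lengths
  res2 <- ses_phylo(tab, d * 7.3, "mntd", pool = c("A", "B", "C"),
                    exhaustive = TRUE)
  expect_equal(res2$ses, res$ses, tolerance = 1e-9)
})

test_that("SES flags degenerate pools and is reproducible under a seed", {
  tr <- simulate_tree(15, seed = 53)
  dc <- patristic_distances(tr)
  tab <- cbind(full = rep(1, 15), part = c(rep(1, 6), rep(0, 9)))
  rownames(tab) <- tr$tip.label
  r1 <- ses_phylo(tab, dc, "mntd", n_null = 99, seed = 5)
  expect_true(r1$undefined[r1$sample == "full"])
  expect_false(r1$undefined[r1$sample == "part"])
  expect_identical(r1, ses_phylo(tab, dc, "mntd", n_null = 99, seed = 5))
})

test_that("betaMNTD agrees with picante::comdistnt", {
  tr <- simulate_tree(18, seed = 54)
  tab <- random_table(18, 5, lambda = 3, seed = 55)
  rownames(tab) <- tr$tip.label
  tab <- tab[rowSums(tab) > 0, ]
  dc <- patristic_distances(tr)[rownames(tab), rownames(tab)]
  res <- beta_nti(tab, dc, n_null = 19, seed = 1)
  ref <- as.matrix(picante::comdistnt(t(tab), dc, abundance.weighted = TRUE))
  expect_equal(res$bmntd[rownames(ref), colnames(ref)], ref, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("identical samples give zero betaMNTD and an undefined betaNTI", {
  tr <- simulate_tree(12, seed = 56)
  dc <- patristic_distances(tr)
  x <- c(rep(5, 6), rep(0, 6))
  tab <- cbind(s1 = x, s2 = x)
  rownames(tab) <- tr$tip.label
  res <- beta_nti(tab, dc, n_null = 49, seed = 2)
  expect_equal(res$bmntd[1, 2], 0)
  expect_true(res$undefined[1, 2])
  expect_true(is.na(res$bnti[1, 2]))
})
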