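test_that("simulated trees are ultrametric, unit depth and reproducible", {
  tr <- simulate_tree(50, seed = 1)
  expect_length(tr$tip.label, 50)
  depths <- ape::node.depth.edgelength(tr)[1:50]
  expect_true(all(abs(depths - 1) < 1e-9))
  expect_identical(ape::write.tree(tr), ape::write.tree(simulate_tree(50, seed = 1)))
  expect_error(simulate_tree(2), "n_tips")
})

test_that("regional pools normalize and flatten as lognormal sd shrinks", {
  tr <- simulate_tree(40, seed = 2)
  pool <- simulate_pool(tr, 1, seed = 3)
  expect_equal(sum(pool$abundance), 1, tolerance = 1e-9)
  flat <- simulate_pool(tr, 1e-4, seed = 3)
  expect_lt(max(flat$abundance) / min(flat$abundance), 1.01)
  expect_error(simulate_pool(tr, 0), "lognormal_sigma")
})

test_that("Brownian optima variance grows with tree depth", {
  vars <- sapply(c(1, 4), function(scale) {
    mean(sapply(1:30, function(sd) {
      tr <- simulate_tree(30, seed = sd)
      tr$edge.length <- tr$edge.length * scale
      stats::var(simulate_pool(tr, 1, seed = sd + 500)$optimum)
    }))
  })
  expect_gt(vars[2], 2 * vars[1])
})

test_that("assembled communities respect depth, seed, and process contrasts", {
  tr <- simulate_tree(60, seed = 4)
  pool <- simulate_pool(tr, 1, seed = 5)
  spec <- scenario_spec("drift", n_samples = 6, depth = 800, seed = 6)
  com <- assemble_communities(pool, tr, spec)
  expect_true(all(colSums(com$table) == 800))
  expect_identical(com$table, assemble_communities(pool, tr, spec)$table)
  expect_identical(com$truth$process, "drift")
  expect_error(scenario_spec("drift", depth = 5), "depth")

  # homogenizing dispersal makes samples mutually closer than drift does
  mean_bc <- function(proc, sd) {
    s <- scenario_spec(proc, n_samples = 6, depth = 800, seed = sd)
    tab <- assemble_communities(pool, tr, s)$table
    mean(vegan::vegdist(t(tab), "bray"))
  }
  wins <- sapply(1:15, function(sd) {
    mean_bc("homogenizing_dispersal", sd) < mean_bc("drift", sd + 100)
  })
  expect_gte(mean(wins), 0.9)
})

test_that("an infinitely weak filter degenerates to drift", {
  tr <- simulate_tree(60, seed = 7)
  pool <- simulate_pool(tr, 1, seed = 8)
  # disjoint sample pairs give independent Bray-Curtis values, as the
  # two-sample test assumes
  iid_bc <- function(tab) {
    S <- ncol(tab)
    sapply(seq(1, S - 1, by = 2), function(i)
      vegan::vegdist(t(tab[, c(i, i + 1)]), "bray")[1])
  }
  ps <- sapply(1:20, function(sd) {
    hs <- assemble_communities(pool, tr,
      scenario_spec("homogeneous_selection", n_samples = 12, depth = 800,
                    sigma = 1e6, seed = sd))$table
    dr <- assemble_communities(pool, tr,
      scenario_spec("drift", n_samples = 12, depth = 800, seed = sd + 50))$table
    suppressWarnings(stats::ks.test(iid_bc(hs), iid_bc(dr))$p.value)
  })
  expect_gte(mean(ps > 0.05), 0.9)
})

test_that("binary traits hit the requested prevalence under both models", {
  tr <- simulate_tree(100, seed = 9)
  for (m in c("brownian_threshold", "random")) {
    tv <- simulate_binary_trait(tr, m, 0.25, seed = 10)
    expect_identical(sum(tv), 25L)
    expect_named(tv, tr$tip.label, ignore.order = TRUE)
  }
  expect_error(simulate_binary_trait(tr, "random", 1.2), "prevalence")
})

test_that("treatment effects preserve depth and move targets as expected", {
  tr <- simulate_tree(80, seed = 11)
  pool <- simulate_pool(tr, 1, seed = 12)
  tab <- assemble_communities(pool, tr,
    scenario_spec("drift", n_samples = 6, depth = 2000, seed = 13))$table
  expect_error(apply_treatment_effect(tab, "nope", 1), "unknown")

  out <- apply_treatment_effect(tab, rownames(tab)[1:5], 2, seed = 14)
  expect_identical(colSums(out), colSums(tab))

  # null effect leaves expected counts unchanged (mean over replicates)
  reps <- sapply(1:60, function(sd)
    apply_treatment_effect(tab, rownames(tab)[1:5], 0, seed = sd)[, 1])
  expect_equal(rowMeans(reps), tab[, 1], tolerance = 0.04 * max(tab[, 1]))

  # +2 log2 on a ~1% taxon realizes ~4x before renormalization correction
  target <- rownames(tab)[which.min(abs(rowSums(tab) / sum(tab) - 0.01))]
  base_share <- mean(tab[target, ] / colSums(tab))
  shares <- sapply(1:100, function(sd) {
    o <- apply_treatment_effect(tab, target, 2, seed = sd + 200)
    mean(o[target, ] / colSums(o))
  })
  expect_equal(mean(shares) / base_share, 4, tolerance = 0.15)
})

test_that("simulate_bundle writes a readable bundle with truth sidecar", {
  dir <- withr::local_tempdir()
  spec <- scenario_spec("dispersal_limitation", n_samples = 5, depth = 300,
                        seed = 42)
  paths <- simulate_bundle(dir, spec, n_tips = 30)
  tab <- read_feature_table(paths$table)
  tr <- read_tree(paths$tree)
  md <- read_sample_metadata(paths$metadata)
  truth <- jsonlite::read_json(paths$truth)
  expect_identical(truth$process, "dispersal_limitation")
  expect_identical(truth$seed, 42L)
  h <- harmonize(tab, tr, md)
  expect_identical(dim(h$table), dim(unclass(tab)))
})
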