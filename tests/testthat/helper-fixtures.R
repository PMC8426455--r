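# Fixtures are built in code: tiny hand trees with known distances, random
# count tables, and a structured two-compartment synthetic community used by
# the pipeline tests.

tree3 <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")
tree4 <- function() ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")

random_table <- function(n_taxa, n_samples, lambda = 15, seed = 1) {
  set.seed(seed)
  matrix(stats::rpois(n_taxa * n_samples, lambda), n_taxa, n_samples,
         dimnames = list(sprintf("t%03d", seq_len(n_taxa)),
                         sprintf("s%02d", seq_len(n_samples))))
}

# two compartments x two treatments, with a clade-targeted drought effect in
# one compartment; returns table, metadata, tree
structured_bundle <- function(seed = 1, n_tips = 80, depth = 1500) {
  tree <- simulate_tree(n_tips, seed = seed)
  pool <- simulate_pool(tree, 1, seed = seed + 1)
  make_comp <- function(s) assemble_communities(
    pool, tree, scenario_spec("drift", n_samples = 10, depth = depth, seed = s))$table
  leaf <- make_comp(seed + 2)
  root <- make_comp(seed + 3)
  targets <- tree$tip.label[1:10]
  leaf[, 6:10] <- apply_treatment_effect(leaf[, 6:10], targets, 2.5,
                                         seed = seed + 4)
  colnames(leaf) <- sprintf("L%02d", 1:10)
  colnames(root) <- sprintf("R%02d", 1:10)
  tab <- cbind(leaf, root)
  md <- sample_metadata(colnames(tab),
                        rep(c("leaf", "root"), each = 10),
                        rep(rep(c("control", "drought"), each = 5), 2))
  list(table = tab, metadata = md, tree = tree)
}

expect_symmetric <- function(m, tol = 1e-9) {
  expect_true(max(abs(m - t(m))) < tol)
  expect_true(all(abs(diag(m)) < tol))
}
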