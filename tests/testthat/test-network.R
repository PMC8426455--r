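monotone_pair_table <- function() {
  base <- 1:10
  tab <- rbind(up1 = base, up2 = base * 3 + 2, down = rev(base) + 5,
               const = rep(4, 10), rare = c(1, rep(0, 9)))
  colnames(tab) <- paste0("s", 1:10)
  tab
}

test_that("edges capture monotone pairs; constant and rare taxa are excluded", {
  net <- build_network(monotone_pair_table(), r_min = 0.6, p_max = 0.05)
  expect_false("const" %in% igraph::V(net)$name)
  expect_false("rare" %in% igraph::V(net)$name)
  e <- igraph::as_data_frame(net)
  key <- paste(pmin(e$from, e$to), pmax(e$from, e$to))
  expect_setequal(key, c("up1 up2", "down up1", "down up2"))
  expect_equal(sort(e$r), c(-1, -1, 1))
  expect_identical(e$sign[order(e$r)], c("negative", "negative", "positive"))
  expect_error(build_network(monotone_pair_table()[, 1:4]), "5 samples")
})

test_that("edge sets are invariant to sample order and monotone in r_min", {
  tab <- random_table(20, 10, seed = 31)
  net1 <- build_network(tab, r_min = 0.4)
  net2 <- build_network(tab[, sample(ncol(tab))], r_min = 0.4)
  edge_key <- function(g) {
    e <- igraph::as_data_frame(g)
    sort(paste(pmin(e$from, e$to), pmax(e$from, e$to)))
  }
  expect_identical(edge_key(net1), edge_key(net2))
  stricter <- build_network(tab, r_min = 0.7)
  expect_true(all(edge_key(stricter) %in% edge_key(net1)))
})

test_that("topology summaries match hand-checked graphs", {
  g4 <- igraph::make_ring(4)
  igraph::V(g4)$name <- letters[1:4]
  t4 <- network_topology(g4)
  expect_equal(t4$average_degree, 2)
  expect_equal(t4$n_clusters, 1)
  expect_true(all(t4$degree_sequence == 2))

  two_tri <- igraph::graph_from_edgelist(
    cbind(c("a", "b", "c", "x", "y", "z"), c("b", "c", "a", "y", "z", "x")),
    directed = FALSE)
  tt <- network_topology(two_tri)
  expect_equal(tt$n_clusters, 2)
  expect_equal(tt$n_edges, 6)

  expect_warning(empty <- network_topology(igraph::make_empty_graph(0, directed = FALSE)),
                 "empty")
  expect_equal(empty$n_vertices, 0)
})

test_that("closeness matches a brute-force shortest-path oracle on P4", {
  p4 <- igraph::make_graph(~ a - b, b - c, c - d)
  topo <- network_topology(p4)
  d <- igraph::distances(p4)
  oracle <- (nrow(d) - 1) / rowSums(d)
  expect_equal(topo$mean_closeness, mean(oracle))
})

test_that("hub scores reproduce the star eigenvector and per-component scaling", {
  star <- igraph::make_star(5, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("hub", paste0("leaf", 1:4))
  hs <- hub_scores(star, top_fraction = 0.05)
  expect_equal(unname(hs$scores["hub"]), 1)
  expect_equal(unname(hs$scores[paste0("leaf", 1:4)]), rep(0.5, 4))
  expect_identical(hs$hubs, "hub")

  # two identical components: both centres reach the global maximum
  two <- igraph::graph_from_edgelist(
    cbind(rep(c("hub1", "hub2"), each = 4),
          paste0("leaf", 1:4, rep(1:2, each = 4))), directed = FALSE)
  hs2 <- hub_scores(two, top_fraction = 0.2)
  expect_equal(unname(hs2$scores[c("hub1", "hub2")]), c(1, 1))

  edge <- igraph::make_graph(~ A - B)
  hse <- hub_scores(edge)
  expect_equal(unname(hse$scores), c(1, 1))
  expect_identical(hub_scores(igraph::make_empty_graph(3, directed = FALSE))$hubs,
                   character(0))
})

test_that("hub scores rank a latent-driver clique above independent taxa", {
  wins <- sapply(1:20, function(sd) {
    set.seed(sd + 600)
    S <- 12
    driver <- rnorm(S)
    clique <- t(sapply(1:6, function(i) rpois(S, exp(2 + 1.5 * driver))))
    noise <- matrix(rpois(10 * S, exp(2)), 10, S)
    tab <- rbind(clique, noise)
    dimnames(tab) <- list(c(paste0("c", 1:6), paste0("n", 1:10)), paste0("s", 1:S))
    hs <- hub_scores(build_network(tab, r_min = 0.6), top_fraction = 0.2)
    top <- names(sort(hs$scores, decreasing = TRUE))[1:3]
    all(grepl("^c", top))
  })
  expect_gte(mean(wins), 0.95)
})

test_that("response ratios divide topology metrics and flag zero controls", {
  t1 <- list(average_degree = 2, n_edges = 50, n_vertices = 20, n_clusters = 2)
  t2 <- list(average_degree = 4, n_edges = 100, n_vertices = 20, n_clusters = 2)
  rr <- response_ratios(t1, t2)
  expect_equal(unname(rr), c(0.5, 0.5, 1, 1))
  expect_equal(unname(response_ratios(t2, t2)), rep(1, 4))
  t0 <- list(average_degree = 0, n_edges = 0, n_vertices = 0, n_clusters = 0)
  expect_warning(rr0 <- response_ratios(t1, t0), "undefined")
  expect_true(all(is.na(rr0)))
})
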