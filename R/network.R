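# Spearman co-occurrence networks and the topology/hub statistics used to
# compare network stability between treatments. Edges are significant strong
# rank correlations (|r| > 0.6, p < 0.05 by default); "clusters" are connected
# components.

#' Build a Spearman co-occurrence network
#'
#' Taxa are filtered by prevalence, constant taxa are excluded (rank
#' correlation undefined), pairwise Spearman correlations use mid-ranks for
#' ties, and p-values come from the t approximation on n - 2 df. An edge is
#' kept iff |r| > r_min and p < p_max (optionally BH-adjusted).
#'
#' @param table feature table (taxa x samples), >= 5 samples.
#' @param r_min minimum absolute Spearman correlation.
#' @param p_max maximum p-value.
#' @param min_prevalence minimum fraction of samples a taxon must occupy.
#' @param adjust_p apply BH correction across candidate edges before the
#'   p_max filter.
#' @return an igraph graph with edge attributes r, p, sign and vertex
#'   attribute abundance (mean relative abundance); class also `campr_network`.
#' @export
build_network <- function(table, r_min = 0.6, p_max = 0.05,
                          min_prevalence = 0.5, adjust_p = FALSE) {
  if (ncol(table) < 5) stopf("need >= 5 samples for rank correlations")
  prev <- rowMeans(table > 0)
  keep <- prev >= min_prevalence
  sub <- table[keep, , drop = FALSE]
  constant <- apply(sub, 1, function(x) length(unique(x)) == 1)
  sub <- sub[!constant, , drop = FALSE]
  n_taxa <- nrow(sub)
  g <- igraph::make_empty_graph(n = n_taxa, directed = FALSE)
  if (n_taxa > 0) {
    igraph::V(g)$name <- rownames(sub)
    igraph::V(g)$abundance <- rowMeans(sweep(table, 2, colSums(table), "/"))[rownames(sub)]
  }
  if (n_taxa >= 2) {
    r <- stats::cor(t(sub), method = "spearman")
    n <- ncol(sub)
    tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
    p[abs(r) >= 1] <- 0
    ut <- upper.tri(r)
    pv <- p[ut]
    if (adjust_p) pv <- stats::p.adjust(pv, "BH")
    sel <- abs(r[ut]) > r_min & pv < p_max
    idx <- which(ut, arr.ind = TRUE)[sel, , drop = FALSE]
    if (nrow(idx)) {
      g <- igraph::add_edges(g, t(idx))
      igraph::E(g)$r <- r[ut][sel]
      igraph::E(g)$p <- pv[sel]
      igraph::E(g)$sign <- ifelse(r[ut][sel] >= 0, "positive", "negative")
    }
  }
  class(g) <- unique(c("campr_network", class(g)))
  g
}

#' Topology summary of a co-occurrence network
#'
#' @param network graph from [build_network()] (any igraph graph works).
#' @return list: n_vertices, n_edges, average_degree, n_clusters (connected
#'   components), mean_closeness (within components), degree_sequence.
#' @export
network_topology <- function(network) {
  nv <- igraph::vcount(network)
  ne <- igraph::ecount(network)
  if (nv == 0) {
    warnf("empty graph: all-zero topology summary")
    return(list(n_vertices = 0, n_edges = 0, average_degree = 0,
                n_clusters = 0, mean_closeness = 0,
                degree_sequence = integer(0)))
  }
  comp <- igraph::components(network)
  deg <- igraph::degree(network)
  # closeness within each component: (n_c - 1) / sum of shortest paths
  clo <- rep(NA_real_, nv)
  for (ci in seq_len(comp$no)) {
    vs <- which(comp$membership == ci)
    if (length(vs) == 1) { clo[vs] <- 0; next }
    d <- igraph::distances(igraph::induced_subgraph(network, vs))
    clo[vs] <- (length(vs) - 1) / rowSums(d)
  }
  list(n_vertices = nv, n_edges = ne,
       average_degree = if (nv > 0) 2 * ne / nv else 0,
       n_clusters = comp$no,
       mean_closeness = mean(clo),
       degree_sequence = stats::setNames(deg, igraph::V(network)$name))
}

#' Hub (keystone) scores
#'
#' Kleinberg hub scores on an undirected graph equal the principal adjacency
#' eigenvector. Scores are computed per connected component (eigenvector of
#' the component's adjacency block, scaled to component max 1) and then
#' globally weighted by the component's spectral radius relative to the
#' largest, so the globally dominant component attains 1.
#'
#' @param network igraph graph.
#' @param top_fraction fraction of nodes reported as hubs (ties kept).
#' @return list(scores = named vector, hubs = character vector of hub ids).
#' @export
hub_scores <- function(network, top_fraction = 0.05) {
  nv <- igraph::vcount(network)
  if (nv == 0 || igraph::ecount(network) == 0)
    return(list(scores = stats::setNames(numeric(0), character(0)), hubs = character(0)))
  comp <- igraph::components(network)
  scores <- rep(0, nv)
  lambda <- numeric(comp$no)
  for (ci in seq_len(comp$no)) {
    vs <- which(comp$membership == ci)
    if (length(vs) == 1) { lambda[ci] <- 0; next }
    A <- igraph::as_adjacency_matrix(igraph::induced_subgraph(network, vs),
                                     sparse = FALSE)
    ev <- eigen(A, symmetric = TRUE)
    lambda[ci] <- ev$values[1]
    v <- abs(ev$vectors[, 1])
    scores[vs] <- if (max(v) > 0) v / max(v) else 0
  }
  lmax <- max(lambda)
  if (lmax > 0) {
    for (ci in seq_len(comp$no)) {
      vs <- which(comp$membership == ci)
      scores[vs] <- scores[vs] * lambda[ci] / lmax
    }
  }
  names(scores) <- igraph::V(network)$name
  n_hub <- max(1L, ceiling(top_fraction * nv))
  ord <- sort(scores, decreasing = TRUE)
  thresh <- ord[min(n_hub, length(ord))]
  hubs <- names(scores)[scores >= thresh & scores > 0]
  list(scores = scores, hubs = hubs)
}

#' Response ratios of topology metrics (treatment / control)
#'
#' @param topology_treatment,topology_control outputs of [network_topology()].
#' @return named numeric vector (average_degree, n_edges, n_vertices,
#'   n_clusters); ratios with a zero control value are NA with a warning.
#' @export
response_ratios <- function(topology_treatment, topology_control) {
  keys <- c("average_degree", "n_edges", "n_vertices", "n_clusters")
  num <- unlist(topology_treatment[keys])
  den <- unlist(topology_control[keys])
  out <- num / den
  bad <- den == 0
  if (any(bad)) {
    warnf("control value zero for %s: ratio undefined",
          paste(keys[bad], collapse = ", "))
    out[bad] <- NA_real_
  }
  stats::setNames(out, keys)
}
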