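# Alpha/beta diversity, ordination and group tests. Conventions follow the
# QIIME2 core-metrics defaults: Shannon in bits (log base 2), Faith's PD
# including the path to the root, weighted UniFrac in its normalized
# (range [0, 1]) variant.

#' Per-sample alpha diversity
#'
#' @param table feature table (taxa x samples), counts.
#' @param metric "shannon" (bits), "observed_features" or "faith_pd".
#' @param tree rooted phylo covering the table's taxa (faith_pd only).
#' @return named numeric vector over samples.
#' @export
alpha_diversity <- function(table, metric = c("shannon", "observed_features", "faith_pd"),
                            tree = NULL) {
  metric <- match.arg(metric)
  if (any(colSums(table) == 0)) stopf("empty sample(s) in table")
  if (metric == "shannon") {
    apply(table, 2, function(x) {
      p <- x[x > 0] / sum(x)
      -sum(p * log2(p))
    })
  } else if (metric == "observed_features") {
    colSums(table > 0)
  } else {
    if (is.null(tree)) stopf("faith_pd requires a tree")
    missing_tips <- setdiff(rownames(table), tree$tip.label)
    if (length(missing_tips))
      stopf("taxa absent from tree: %s", paste(utils::head(missing_tips, 5), collapse = ", "))
    comm <- t(table)
    # pad community matrix to all tips so picante keeps the root path
    pad <- setdiff(tree$tip.label, colnames(comm))
    if (length(pad)) {
      comm <- cbind(comm, matrix(0, nrow(comm), length(pad),
                                 dimnames = list(rownames(comm), pad)))
    }
    res <- picante::pd(comm, tree, include.root = TRUE)
    stats::setNames(res$PD, rownames(res))
  }
}

#' Pairwise beta diversity
#'
#' Bray-Curtis on raw counts, or the normalized weighted UniFrac
#' `sum(b * |p - q|) / sum(b * (p + q))` over branches, with p, q the relative
#' abundances descending from each branch.
#'
#' @param table feature table (taxa x samples).
#' @param metric "bray_curtis" or "weighted_unifrac".
#' @param tree rooted phylo (weighted_unifrac only).
#' @return a symmetric `dist`-convertible matrix with zero diagonal.
#' @export
beta_diversity <- function(table, metric = c("bray_curtis", "weighted_unifrac"),
                           tree = NULL) {
  metric <- match.arg(metric)
  if (metric == "bray_curtis") {
    d <- as.matrix(vegan::vegdist(t(table), method = "bray"))
    dimnames(d) <- list(colnames(table), colnames(table))
    return(d)
  }
  if (is.null(tree)) stopf("weighted_unifrac requires a tree")
  missing_tips <- setdiff(rownames(table), tree$tip.label)
  if (length(missing_tips))
    stopf("taxa absent from tree: %s", paste(utils::head(missing_tips, 5), collapse = ", "))
  tr <- ape::keep.tip(tree, intersect(tree$tip.label, rownames(table)))
  rel <- sweep(table[tr$tip.label, , drop = FALSE], 2, colSums(table), "/")
  n_tip <- length(tr$tip.label)
  n_node <- n_tip + tr$Nnode
  # branch_mass[v, s] = relative abundance descending from node v in sample s
  branch_mass <- matrix(0, n_node, ncol(rel))
  branch_mass[seq_len(n_tip), ] <- rel
  # postorder visits children before parents: accumulate mass rootwards
  for (e in ape::postorder(tr)) {
    par <- tr$edge[e, 1]; child <- tr$edge[e, 2]
    branch_mass[par, ] <- branch_mass[par, ] + branch_mass[child, ]
  }
  S <- ncol(rel)
  d <- matrix(0, S, S, dimnames = list(colnames(rel), colnames(rel)))
  blen <- tr$edge.length
  child_mass <- branch_mass[tr$edge[, 2], , drop = FALSE]
  for (i in seq_len(S - 1)) {
    for (j in (i + 1):S) {
      num <- sum(blen * abs(child_mass[, i] - child_mass[, j]))
      den <- sum(blen * (child_mass[, i] + child_mass[, j]))
      d[i, j] <- d[j, i] <- if (den > 0) num / den else 0
    }
  }
  d
}

#' Principal coordinates analysis
#'
#' Classical MDS on the Gower-centered matrix. Negative eigenvalues are
#' reported (not corrected) and flagged.
#'
#' @param dm square distance matrix.
#' @param k number of axes (default 2; must be <= n - 1).
#' @return list(coordinates, eigenvalues, proportion_explained,
#'   negative_eigenvalues).
#' @export
pcoa <- function(dm, k = 2) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (k > n - 1) stopf("k must be <= n - 1")
  mds <- suppressWarnings(stats::cmdscale(stats::as.dist(dm), k = k, eig = TRUE))
  eig <- mds$eig
  pos <- sum(eig[eig > 0])
  coords <- mds$points
  if (!is.null(coords) && ncol(coords) < k) {
    # degenerate configurations can yield fewer axes than requested
    coords <- cbind(coords, matrix(0, n, k - ncol(coords)))
  }
  rownames(coords) <- rownames(dm)
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  list(coordinates = coords,
       eigenvalues = eig,
       proportion_explained = if (pos > 0) pmax(eig, 0) / pos else rep(0, length(eig)),
       negative_eigenvalues = any(eig < -1e-8 * max(abs(eig), 1)))
}

#' PERMANOVA on a distance matrix
#'
#' Pseudo-F from among/within sums of squared distances with label
#' permutation; p = (1 + #permuted F >= observed F) / (1 + n_perm).
#'
#' @param dm square distance matrix.
#' @param groups factor of group labels, one per sample.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return list(F, p, df).
#' @export
permanova <- function(dm, groups, n_perm = 999, seed = NULL) {
  dm <- as.matrix(dm)
  groups <- factor(groups)
  if (any(table(groups) < 2)) stopf("every group needs >= 2 samples")
  df <- data.frame(g = groups)
  with_seed(seed, {
    fit <- vegan::adonis2(stats::as.dist(dm) ~ g, data = df,
                          permutations = n_perm)
    list(F = fit$F[1], p = fit$`Pr(>F)`[1],
         df = c(fit$Df[1], fit$Df[2]))
  })
}

#' Pairwise PERMANOVA with Benjamini-Hochberg correction
#'
#' @inheritParams permanova
#' @return data.frame with one row per group pair: F, p, q (BH).
#' @export
pairwise_permanova <- function(dm, groups, n_perm = 999, seed = NULL) {
  groups <- factor(groups)
  levs <- levels(groups)
  pairs <- utils::combn(levs, 2)
  res <- apply(pairs, 2, function(pr) {
    keep <- groups %in% pr
    fit <- permanova(as.matrix(dm)[keep, keep, drop = FALSE],
                     droplevels(groups[keep]), n_perm, seed)
    c(F = fit$F, p = fit$p)
  })
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    F = res["F", ], p = res["p", ])
  out$q <- stats::p.adjust(out$p, "BH")
  out
}

#' Kruskal-Wallis comparison of a numeric variable across groups
#'
#' Tie-corrected H; if all values are identical H = 0 and p = 1 by convention.
#'
#' @param values numeric vector.
#' @param groups factor of group labels.
#' @return list(H, p).
#' @export
compare_groups <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stopf("need >= 2 groups")
  if (length(unique(values)) == 1) return(list(H = 0, p = 1))
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), p = kt$p.value)
}
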