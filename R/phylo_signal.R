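# Phylogenetic signal of a binary trait: the Fritz-Purvis dispersion
# statistic D (anchored at 1 for a phylogenetically random trait and 0 for a
# Brownian-threshold-conserved trait) and the consenTRAIT mean trait depth
# tau_D (mean phylogenetic depth of the clades within which the trait is
# consistently present).

# Sum of sister-clade differences: node values estimated by successive
# equal-weights averaging of child values from the tips to the root; the
# statistic is the sum over internal nodes of the mean absolute difference
# between child values (binary trees: |v1 - v2|).
fp_sum_diff <- function(tree, x) {
  ntip <- length(tree$tip.label)
  tipval <- as.numeric(x[tree$tip.label])
  children <- split(tree$edge[, 2], tree$edge[, 1])
  total <- 0
  eval_node <- function(node) {
    if (node <= ntip) return(tipval[node])
    v <- vapply(children[[as.character(node)]], eval_node, numeric(1))
    # binary nodes contribute |v1 - v2|; polytomies the scaled mean deviation
    total <<- total + mean(abs(v - mean(v))) * 2 * (length(v) - 1) / length(v)
    mean(v)
  }
  eval_node(ntip + 1L)
  total
}

#' Fritz-Purvis D for a binary trait
#'
#' D = (S_obs - mean S_brownian) / (mean S_random - mean S_brownian), where S
#' is the sum of sister-clade differences, the random reference shuffles tip
#' states and the Brownian reference simulates a continuous Brownian character
#' thresholded at the observed prevalence. D ~ 1 indicates a phylogenetically
#' random trait, D ~ 0 Brownian-level conservation, D < 0 stronger clumping.
#'
#' @param tree rooted phylo.
#' @param trait named 0/1 vector over the tips (both states required).
#' @param n_perm random permutations and Brownian simulations.
#' @param seed integer seed.
#' @return list(D, p_random, p_brownian): p_random is the add-one-smoothed
#'   fraction of random references at least as clumped as observed (S <= S_obs);
#'   p_brownian the fraction of Brownian references at least as overdispersed
#'   (S >= S_obs).
#' @export
fritz_purvis_d <- function(tree, trait, n_perm = 1000, seed = NULL) {
  trait <- trait[tree$tip.label]
  if (any(is.na(trait))) stopf("trait must cover all tree tips")
  k <- sum(trait == 1)
  if (k == 0 || k == length(trait)) stopf("no variation in trait")
  s_obs <- fp_sum_diff(tree, trait)
  with_seed(seed, {
    s_rand <- vapply(seq_len(n_perm), function(i) {
      sh <- stats::setNames(sample(trait), names(trait))
      fp_sum_diff(tree, sh)
    }, numeric(1))
    # the sister-difference sum only sees the bipartition, so thresholding at
    # min(k, n - k) positives is distribution-equivalent and makes D exactly
    # invariant under swapping the 0/1 labels
    m <- min(k, length(trait) - k)
    s_brown <- vapply(seq_len(n_perm), function(i) {
      z <- ape::rTraitCont(tree, model = "BM", sigma = 1)
      thr <- sort(z, decreasing = TRUE)[m]
      bt <- stats::setNames(as.numeric(z >= thr), names(z))
      fp_sum_diff(tree, bt)
    }, numeric(1))
    D <- (s_obs - mean(s_brown)) / (mean(s_rand) - mean(s_brown))
    list(D = D,
         p_random = (sum(s_rand <= s_obs) + 1) / (n_perm + 1),
         p_brownian = (sum(s_brown >= s_obs) + 1) / (n_perm + 1))
  })
}

#' consenTRAIT mean trait depth
#'
#' Finds the maximal clades in which at least `consensus` of the tips carry
#' the trait; each clade contributes the mean patristic distance from its
#' root node to its tips. Positive tips outside any qualifying clade
#' contribute half their terminal branch length as singletons. tau_D is the
#' mean over clades and singletons.
#'
#' @param tree rooted phylo with branch lengths.
#' @param trait named 0/1 vector over the tips (>= 1 positive).
#' @param consensus minimum positive fraction within a qualifying clade.
#' @return list(tau_d, clades = list of tip sets, depths).
#' @export
consentrait <- function(tree, trait, consensus = 0.9) {
  trait <- trait[tree$tip.label]
  if (any(is.na(trait))) stopf("trait must cover all tree tips")
  if (sum(trait == 1) == 0) stopf("no positive tips")
  ntip <- length(tree$tip.label)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  edge_len <- stats::setNames(tree$edge.length, tree$edge[, 2])
  node_depth <- ape::node.depth.edgelength(tree)  # root-to-node distances
  tips_under <- function(node) {
    if (node <= ntip) return(node)
    unlist(lapply(children[[as.character(node)]], tips_under), use.names = FALSE)
  }
  clades <- list(); depths <- numeric(0)
  stack <- ntip + 1L
  while (length(stack)) {
    node <- stack[[1]]; stack <- stack[-1]
    tips <- tips_under(node)
    if (length(tips) >= 2 && mean(trait[tips]) >= consensus) {
      clades[[length(clades) + 1]] <- tree$tip.label[tips]
      depths <- c(depths, mean(node_depth[tips] - node_depth[node]))
    } else if (length(tips) >= 2) {
      stack <- c(as.list(children[[as.character(node)]]), stack)
    } else if (trait[tips] == 1) {
      # singleton positive tip: half its terminal branch
      clades[[length(clades) + 1]] <- tree$tip.label[tips]
      depths <- c(depths, edge_len[as.character(tips)] / 2)
    }
  }
  list(tau_d = mean(depths), clades = clades, depths = unname(depths))
}
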