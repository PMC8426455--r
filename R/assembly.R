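# Five-process partition of community turnover. A two-stage decision rule is
# applied per sample pair: |betaNTI| > 2 assigns selection (sign gives
# heterogeneous vs homogeneous); otherwise the Bray-Curtis Raup-Crick index
# assigns dispersal limitation (RC > 0.95), homogenizing dispersal
# (RC < -0.95) or drift (the residual). The phylogenetic-bin variant runs
# both null models within clades of bounded phylogenetic depth and aggregates
# pair-level calls with bin abundance weights (the iCAMP idea).

PROCESS_LEVELS <- c("heterogeneous_selection", "homogeneous_selection",
                    "dispersal_limitation", "homogenizing_dispersal", "drift")

# Null communities for the Raup-Crick model, drawn independently per sample:
# richness equals the observed richness, taxa are picked without replacement
# with probability proportional to pool occupancy, one individual seeds each
# picked taxon and the remaining individuals are multinomial with pool
# abundance weights. Returns a taxa x n_null count matrix.
rc_null_draws <- function(richness, depth, occupancy, abundance, n_null) {
  n_taxa <- length(occupancy)
  out <- matrix(0, n_taxa, n_null)
  for (b in seq_len(n_null)) {
    sel <- sample.int(n_taxa, richness, prob = occupancy)
    cnt <- rep(1, richness)
    extra <- depth - richness
    if (extra > 0)
      cnt <- cnt + as.numeric(stats::rmultinom(1, extra, abundance[sel]))
    out[sel, b] <- cnt
  }
  out
}

bray_cols <- function(A, B) colSums(abs(A - B)) / colSums(A + B)

#' Bray-Curtis based Raup-Crick index for all sample pairs
#'
#' RC = 2 * (fraction of null Bray-Curtis values below the observed one,
#' counting ties as half) - 1, so RC is in [-1, 1]; RC > 0.95 means the pair
#' shares fewer taxa/abundance than expected by chance, RC < -0.95 more.
#'
#' @param table feature table (taxa x samples), >= 2 samples.
#' @param n_null null draws per sample.
#' @param seed integer seed.
#' @return symmetric matrix of RC values with zero diagonal.
#' @export
rc_bray <- function(table, n_null = 999, seed = NULL) {
  if (ncol(table) < 2) stopf("need >= 2 samples")
  pool <- rowSums(table) > 0
  tab <- table[pool, , drop = FALSE]
  if (nrow(tab) < 2) stopf("pool must contain >= 2 taxa")
  occ <- rowMeans(tab > 0)
  ab <- rowSums(tab) / sum(tab)
  S <- ncol(tab)
  obs <- as.matrix(vegan::vegdist(t(tab), method = "bray"))
  with_seed(seed, {
    nulls <- lapply(seq_len(S), function(s) {
      rc_null_draws(sum(tab[, s] > 0), sum(tab[, s]), occ, ab, n_null)
    })
    rc <- matrix(0, S, S, dimnames = list(colnames(tab), colnames(tab)))
    for (i in seq_len(S - 1)) {
      for (j in (i + 1):S) {
        bc <- bray_cols(nulls[[i]], nulls[[j]])
        frac <- (sum(bc < obs[i, j] - 1e-12) +
                   0.5 * sum(abs(bc - obs[i, j]) <= 1e-12)) / n_null
        rc[i, j] <- rc[j, i] <- 2 * frac - 1
      }
    }
    rc
  })
}

#' Two-stage betaNTI + Raup-Crick process assignment
#'
#' betaNTI > 2: heterogeneous selection; betaNTI < -2: homogeneous selection;
#' otherwise RC > 0.95: dispersal limitation; RC < -0.95: homogenizing
#' dispersal; else drift.
#'
#' @param bnti_matrix,rc_matrix aligned symmetric matrices over samples.
#' @return list(pairs = data.frame(sample_a, sample_b, bnti, rc, process),
#'   fractions = named shares of the five processes summing to 1).
#' @export
stegen_partition <- function(bnti_matrix, rc_matrix) {
  bnti_matrix <- as.matrix(bnti_matrix); rc_matrix <- as.matrix(rc_matrix)
  stopifnot(identical(dim(bnti_matrix), dim(rc_matrix)))
  ids <- colnames(bnti_matrix) %||% as.character(seq_len(ncol(bnti_matrix)))
  ut <- which(upper.tri(bnti_matrix), arr.ind = TRUE)
  bnti <- bnti_matrix[upper.tri(bnti_matrix)]
  rc <- rc_matrix[upper.tri(rc_matrix)]
  keep <- !is.na(bnti)
  if (any(!keep)) warnf("excluding %d pair(s) with missing betaNTI", sum(!keep))
  proc <- assign_process(bnti[keep], rc[keep])
  pairs <- data.frame(sample_a = ids[ut[keep, 1]], sample_b = ids[ut[keep, 2]],
                      bnti = bnti[keep], rc = rc[keep], process = proc,
                      stringsAsFactors = FALSE)
  frac <- prop.table(table(factor(proc, PROCESS_LEVELS)))
  list(pairs = pairs, fractions = c(unclass(frac)))
}

assign_process <- function(bnti, rc) {
  ifelse(bnti > 2, "heterogeneous_selection",
    ifelse(bnti < -2, "homogeneous_selection",
      ifelse(rc > 0.95, "dispersal_limitation",
        ifelse(rc < -0.95, "homogenizing_dispersal", "drift"))))
}

#' Partition taxa into phylogenetic bins
#'
#' Greedy root-to-tip traversal: a clade becomes a bin once its maximum
#' within-clade patristic distance is <= `ds`; bins smaller than `n_min` are
#' then merged with the phylogenetically nearest bin until all bins reach
#' `n_min` (or one bin remains).
#'
#' @param tree rooted phylo covering `taxa`.
#' @param taxa taxa to bin (default: all tips).
#' @param ds maximum within-bin patristic distance before merging.
#' @param n_min minimum bin size after merging.
#' @return list of character vectors (bins partitioning `taxa`).
#' @export
phylo_binning <- function(tree, taxa = tree$tip.label, ds = 0.2, n_min = 24) {
  if (ds <= 0) stopf("ds must be > 0")
  tr <- ape::keep.tip(tree, intersect(tree$tip.label, taxa))
  d <- patristic_distances(tr)
  ntip <- length(tr$tip.label)
  root <- ntip + 1L
  children <- split(tr$edge[, 2], tr$edge[, 1])
  tips_under <- function(node) {
    if (node <= ntip) return(tr$tip.label[node])
    unlist(lapply(children[[as.character(node)]], tips_under), use.names = FALSE)
  }
  bins <- list()
  stack <- root
  while (length(stack)) {
    node <- stack[[1]]; stack <- stack[-1]
    tips <- tips_under(node)
    if (length(tips) == 1 || max(d[tips, tips]) <= ds) {
      bins[[length(bins) + 1]] <- tips
    } else {
      stack <- c(as.list(children[[as.character(node)]]), stack)
    }
  }
  # merge undersized bins with their phylogenetically nearest neighbor;
  # distance ties break toward the smaller neighbor to keep bins balanced
  while (length(bins) > 1 && min(lengths(bins)) < n_min) {
    i <- which.min(lengths(bins))
    dists <- vapply(seq_along(bins), function(j) {
      if (j == i) return(Inf)
      min(d[bins[[i]], bins[[j]]])
    }, numeric(1))
    cand <- which(dists <= min(dists) + 1e-12)
    j <- cand[which.min(lengths(bins)[cand])]
    bins[[j]] <- c(bins[[j]], bins[[i]])
    bins[[i]] <- NULL
  }
  bins
}

#' Phylogenetic-bin five-process partition of turnover
#'
#' For every phylogenetic bin and sample pair, a bin-restricted betaNTI
#' (taxa labels shuffled within the bin) and a bin-restricted Raup-Crick index
#' are computed and classified by the two-stage rule; community-level process
#' fractions aggregate the calls with weights equal to the mean relative
#' abundance of the bin in the two samples of the pair (renormalized over the
#' bins usable for that pair).
#'
#' @param table feature table (taxa x samples).
#' @param tree rooted phylo covering the table's taxa.
#' @param n_null null randomizations per bin.
#' @param ds,n_min binning parameters (see [phylo_binning()]).
#' @param seed integer seed.
#' @param pool "tree" (default) shuffles taxa over all tips of the supplied
#'   tree, treating it as the regional pool, so taxa that the regional tree
#'   carries but the table never records still count as available niches in
#'   the null; "table" restricts the null universe to observed taxa.
#' @return object of class `assembly_partition`: list(fractions, pairs, bins,
#'   dominant) — fractions sum to 1 over the five processes.
#' @export
icamp_partition <- function(table, tree, n_null = 999, ds = 0.2, n_min = 24,
                            seed = NULL, pool = c("tree", "table")) {
  pool <- match.arg(pool)
  observed <- rownames(table)[rowSums(table) > 0]
  universe <- if (pool == "tree") tree$tip.label else observed
  if (length(setdiff(observed, universe)))
    stopf("tree does not cover all observed taxa")
  tab <- matrix(0, length(universe), ncol(table),
                dimnames = list(universe, colnames(table)))
  tab[observed, ] <- table[observed, ]
  bins <- phylo_binning(tree, universe, ds = ds, n_min = n_min)
  dfull <- patristic_distances(ape::keep.tip(tree, universe))
  S <- ncol(tab)
  npair <- S * (S - 1) / 2
  pair_idx <- which(upper.tri(matrix(0, S, S)), arr.ind = TRUE)
  totals <- colSums(tab)
  weights <- matrix(0, npair, length(bins))
  calls <- matrix(NA_character_, npair, length(bins))
  with_seed(seed, {
    for (b in seq_along(bins)) {
      taxa <- bins[[b]]
      sub <- tab[taxa, , drop = FALSE]
      bin_share <- colSums(sub) / totals
      w <- (bin_share[pair_idx[, 1]] + bin_share[pair_idx[, 2]]) / 2
      present <- colSums(sub > 0)
      if (length(taxa) < 2) next
      dbin <- dfull[taxa, taxa]
      freq <- sweep(sub, 2, pmax(colSums(sub), 1), "/")
      obs <- beta_mntd_matrix(freq, dbin)
      acc <- matrix(0, S, S); acc2 <- matrix(0, S, S)
      for (r in seq_len(n_null)) {
        perm <- sample(length(taxa))
        nb <- beta_mntd_matrix(freq, dbin[perm, perm])
        acc <- acc + nb
        acc2 <- acc2 + nb^2
      }
      mu <- acc / n_null
      sdev <- sqrt(pmax((acc2 - n_null * mu^2) / (n_null - 1), 0))
      bnti <- (obs - mu) / ifelse(sdev > 0, sdev, NA)
      # a bin with no phylogenetic turnover at all (observed equals every
      # null draw) carries no selection signal: fall through to the RC stage
      bnti[sdev == 0 & abs(obs - mu) < 1e-12] <- 0
      # bin-restricted Raup-Crick: null draws per sample within the bin
      occ <- rowMeans(sub > 0)
      ab <- rowSums(sub) / sum(sub)
      obs_bc <- suppressWarnings(as.matrix(vegan::vegdist(t(sub), method = "bray")))
      nulls <- lapply(seq_len(S), function(s) {
        if (present[s] == 0) return(NULL)
        rc_null_draws(present[s], sum(sub[, s]), occ, ab, n_null)
      })
      for (pr in seq_len(npair)) {
        i <- pair_idx[pr, 1]; j <- pair_idx[pr, 2]
        # usable only when both samples have bin members and the bin carries
        # >= 2 taxa across the pair (otherwise turnover is undefined)
        if (present[i] == 0 || present[j] == 0 ||
            length(unique(c(which(sub[, i] > 0), which(sub[, j] > 0)))) < 2 ||
            is.na(bnti[i, j]))
          next
        bc <- bray_cols(nulls[[i]], nulls[[j]])
        frac <- (sum(bc < obs_bc[i, j] - 1e-12) +
                   0.5 * sum(abs(bc - obs_bc[i, j]) <= 1e-12)) / n_null
        rcv <- 2 * frac - 1
        calls[pr, b] <- assign_process(bnti[i, j], rcv)
        weights[pr, b] <- w[pr]
      }
    }
  })
  usable <- !is.na(calls)
  if (!any(usable)) stopf("no usable bin/pair combinations")
  wsum <- rowSums(weights * usable)
  frac <- stats::setNames(numeric(length(PROCESS_LEVELS)), PROCESS_LEVELS)
  for (pr in seq_len(npair)) {
    if (wsum[pr] == 0) next
    for (b in seq_along(bins)) {
      if (!usable[pr, b]) next
      frac[calls[pr, b]] <- frac[calls[pr, b]] + weights[pr, b] / wsum[pr]
    }
  }
  frac <- frac / sum(frac)
  structure(list(fractions = frac,
                 pairs = data.frame(sample_a = colnames(tab)[pair_idx[, 1]],
                                    sample_b = colnames(tab)[pair_idx[, 2]]),
                 bins = bins,
                 dominant = names(frac)[which.max(frac)]),
            class = "assembly_partition")
}

#' @export
print.assembly_partition <- function(x, ...) {
  cat("Five-process assembly partition\n")
  cat(sprintf("  bins: %d, pairs: %d\n", length(x$bins), nrow(x$pairs)))
  for (p in names(x$fractions))
    cat(sprintf("  %-24s %6.3f\n", p, x$fractions[p]))
  cat(sprintf("  dominant: %s\n", x$dominant))
  invisible(x)
}
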