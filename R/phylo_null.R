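# Phylogenetic alpha and beta null models: MPD/MNTD, their standardized
# effect sizes against a taxa-label-shuffling null, and the between-sample
# betaMNTD/betaNTI. The null scheme shuffles taxon labels on the patristic
# distance matrix restricted to the species pool (the picante/Stegen
# "taxa.labels" standard); SES uses the sample (n - 1) standard deviation of
# the null draws.

MAX_POOL <- 5000

#' Patristic (tip-to-tip) distance matrix
#'
#' @param tree rooted phylo with branch lengths.
#' @return dense symmetric matrix of summed branch lengths between tips.
#' @export
patristic_distances <- function(tree) {
  if (length(tree$tip.label) > MAX_POOL)
    stopf("tree has > %d tips; dense patristic matrix refused", MAX_POOL)
  stats::cophenetic(tree)
}

#' Mean pairwise and mean nearest-taxon distance of one community
#'
#' MPD averages distances over distinct taxon pairs (abundance-weighted:
#' weights a_i * a_j); MNTD averages each taxon's distance to its nearest
#' other taxon (abundance-weighted: weights a_i).
#'
#' @param sample_taxa character vector of taxa present (>= 2).
#' @param dcache patristic distance matrix covering the taxa.
#' @param abundances optional named abundances for weighting.
#' @return list(mpd, mntd); NA with a flag when fewer than 2 taxa.
#' @export
mpd_mntd <- function(sample_taxa, dcache, abundances = NULL) {
  k <- length(sample_taxa)
  if (k < 2) return(list(mpd = NA_real_, mntd = NA_real_, undefined = TRUE))
  d <- dcache[sample_taxa, sample_taxa, drop = FALSE]
  nn <- apply(d + diag(Inf, k), 1, min)
  if (is.null(abundances)) {
    list(mpd = mean(d[upper.tri(d)]), mntd = mean(nn), undefined = FALSE)
  } else {
    a <- abundances[sample_taxa]
    a <- a / sum(a)
    w <- outer(a, a)
    list(mpd = sum(w[upper.tri(w)] * d[upper.tri(d)]) / sum(w[upper.tri(w)]),
         mntd = sum(a * nn), undefined = FALSE)
  }
}

#' Standardized effect size of MPD or MNTD per sample
#'
#' Null communities are generated by shuffling taxon labels on the distance
#' matrix restricted to the pool (taxa observed in the table by default), so
#' each null draw replaces the sample's taxa by a uniformly random same-size
#' subset of the pool. SES = (obs - mean(null)) / sd(null); NTI = -SES_MNTD.
#' With `exhaustive = TRUE` (small pools only) all distinct subsets are
#' enumerated instead of sampled.
#'
#' @param table feature table (taxa x samples).
#' @param dcache patristic distance matrix covering the pool.
#' @param metric "mntd" or "mpd".
#' @param n_null number of null randomizations.
#' @param seed integer seed.
#' @param pool character vector defining the species pool (default: taxa with
#'   nonzero total count in `table`).
#' @param abundance_weighted weight by within-sample relative abundance
#'   (nulls then shuffle which taxa carry the abundances).
#' @param exhaustive enumerate all subsets (unweighted only; pool choose k
#'   must be <= 10000).
#' @return data.frame per sample: obs, null_mean, null_sd, ses, nti (mntd
#'   only), undefined flag.
#' @export
ses_phylo <- function(table, dcache, metric = c("mntd", "mpd"), n_null = 999,
                      seed = NULL, pool = NULL, abundance_weighted = FALSE,
                      exhaustive = FALSE) {
  metric <- match.arg(metric)
  pool <- pool %||% rownames(table)[rowSums(table) > 0]
  if (length(pool) > MAX_POOL) stopf("pool exceeds %d taxa", MAX_POOL)
  dpool <- dcache[pool, pool]
  one_metric <- function(idx, a = NULL) {
    k <- length(idx)
    d <- dpool[idx, idx, drop = FALSE]
    if (metric == "mpd") {
      if (is.null(a)) return(mean(d[upper.tri(d)]))
      w <- outer(a, a)
      return(sum(w[upper.tri(w)] * d[upper.tri(d)]) / sum(w[upper.tri(w)]))
    }
    nn <- apply(d + diag(Inf, k), 1, min)
    if (is.null(a)) mean(nn) else sum(a * nn)
  }
  res <- with_seed(seed, {
    lapply(colnames(table), function(s) {
      x <- table[pool, s]
      idx <- which(x > 0)
      k <- length(idx)
      if (k < 2)
        return(data.frame(sample = s, obs = NA, null_mean = NA, null_sd = NA,
                          ses = NA, undefined = TRUE))
      a <- if (abundance_weighted) x[idx] / sum(x[idx]) else NULL
      obs <- one_metric(idx, a)
      if (k == length(pool))
        return(data.frame(sample = s, obs = obs, null_mean = obs, null_sd = 0,
                          ses = NA, undefined = TRUE))
      if (exhaustive) {
        if (abundance_weighted) stopf("exhaustive mode is unweighted only")
        if (choose(length(pool), k) > 10000) stopf("too many subsets to enumerate")
        subs <- utils::combn(length(pool), k)
        nulls <- apply(subs, 2, one_metric)
      } else {
        nulls <- vapply(seq_len(n_null), function(i) {
          one_metric(sample(length(pool), k), a)
        }, numeric(1))
      }
      mu <- mean(nulls); sdev <- stats::sd(nulls)
      data.frame(sample = s, obs = obs, null_mean = mu, null_sd = sdev,
                 ses = if (sdev > 0) (obs - mu) / sdev else NA,
                 undefined = sdev == 0)
    })
  })
  out <- do.call(rbind, res)
  if (metric == "mntd") out$nti <- -out$ses
  out
}

# betaMNTD between all sample pairs given a distance matrix over the pool and
# a frequency matrix (taxa x samples, columns sum to 1 over present taxa).
# For each pair (i, j): mean over taxa in i (weighted) of the nearest-taxon
# distance to community j, averaged with the reverse direction. A taxon
# shared by both communities has nearest-taxon distance 0.
beta_mntd_matrix <- function(freq, dmat) {
  S <- ncol(freq)
  present <- freq > 0
  # dmin[t, s] = distance from taxon t to the nearest taxon present in sample s
  dmin <- vapply(seq_len(S), function(s) {
    cols <- which(present[, s])
    if (length(cols) == 0) return(rep(NA_real_, nrow(freq)))
    if (length(cols) == 1) dmat[, cols] else
      do.call(pmin, lapply(cols, function(cc) dmat[, cc]))
  }, numeric(nrow(freq)))
  half <- t(freq) %*% dmin           # half[i, j] = sum_t f[t,i] * dmin[t, j]
  b <- (half + t(half)) / 2
  diag(b) <- diag(half)
  b
}

#' Pairwise beta nearest-taxon index (betaNTI)
#'
#' betaMNTD between sample pairs (abundance-weighted by default), with a null
#' generated by shuffling taxon labels on the pooled distance matrix;
#' betaNTI = (obs - mean(null)) / sd(null). |betaNTI| > 2 is conventionally
#' read as deterministic selection.
#'
#' @param table feature table (taxa x samples), >= 2 samples.
#' @param dcache patristic distance matrix covering the table's taxa.
#' @param n_null null randomizations.
#' @param seed integer seed.
#' @param abundance_weighted weight by relative abundances (default TRUE).
#' @return list(bnti, bmntd, undefined): symmetric matrices over samples.
#' @export
beta_nti <- function(table, dcache, n_null = 999, seed = NULL,
                     abundance_weighted = TRUE) {
  if (ncol(table) < 2) stopf("need >= 2 samples")
  pool <- rownames(table)[rowSums(table) > 0]
  if (length(pool) < 2) stopf("pool must contain >= 2 taxa")
  tab <- table[pool, , drop = FALSE]
  freq <- if (abundance_weighted) sweep(tab, 2, colSums(tab), "/") else
    sweep(tab > 0, 2, colSums(tab > 0), "/")
  dmat <- dcache[pool, pool]
  obs <- beta_mntd_matrix(freq, dmat)
  S <- ncol(tab)
  with_seed(seed, {
    acc <- matrix(0, S, S); acc2 <- matrix(0, S, S)
    for (b in seq_len(n_null)) {
      perm <- sample(length(pool))
      nb <- beta_mntd_matrix(freq, dmat[perm, perm])
      acc <- acc + nb
      acc2 <- acc2 + nb^2
    }
    mu <- acc / n_null
    sdev <- sqrt(pmax((acc2 - n_null * mu^2) / (n_null - 1), 0))
    bnti <- (obs - mu) / sdev
    undefined <- sdev == 0
    bnti[undefined] <- NA
    dimnames(bnti) <- dimnames(obs) <- list(colnames(tab), colnames(tab))
    diag(bnti) <- 0
    list(bnti = bnti, bmntd = obs, undefined = undefined)
  })
}
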