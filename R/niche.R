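# Levins' niche breadth (habitat unit = sample), the community-level mean
# Bcom, and a permutation-based generalist/specialist classifier. The null
# for a taxon redistributes its individuals across samples in proportion to
# sample depths (the per-taxon marginal of reshuffling all individuals while
# preserving per-sample totals), so breadth is judged against what random
# placement would produce under the same sampling effort.

#' Levins' niche breadth per taxon
#'
#' B_j = 1 / sum_i P_ij^2 where P_ij is the proportion of taxon j's
#' individuals found in sample i; 1 <= B <= number of samples. All-zero taxa
#' are excluded.
#'
#' @param table feature table (taxa x samples).
#' @return data.frame: taxon, B, n_occupied.
#' @export
levins_b <- function(table) {
  keep <- rowSums(table) > 0
  tab <- table[keep, , drop = FALSE]
  P <- sweep(tab, 1, rowSums(tab), "/")
  data.frame(taxon = rownames(tab),
             B = 1 / rowSums(P^2),
             n_occupied = rowSums(tab > 0),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Community-level niche breadth (Bcom)
#'
#' Unweighted mean of Levins' B over the taxa occurring in each sample
#' (abundance-weighted variant available).
#'
#' @param table feature table (taxa x samples).
#' @param breadths data.frame from [levins_b()] (recomputed if NULL).
#' @param weighted weight members by relative abundance.
#' @return named numeric vector of Bcom per sample.
#' @export
community_bcom <- function(table, breadths = NULL, weighted = FALSE) {
  if (any(colSums(table) == 0)) stopf("empty sample(s)")
  breadths <- breadths %||% levins_b(table)
  B <- stats::setNames(breadths$B, breadths$taxon)
  vapply(colnames(table), function(s) {
    x <- table[, s]
    members <- rownames(table)[x > 0]
    if (!weighted) return(mean(B[members]))
    w <- x[x > 0] / sum(x)
    sum(w * B[members])
  }, numeric(1))
}

#' Generalist/specialist classification by permutation null on Levins' B
#'
#' For each taxon, `n_perm` null placements redistribute its total count
#' across samples with probabilities proportional to sample depths; the
#' observed B is compared to the two-tailed alpha quantiles of the null B
#' distribution. Above the upper quantile: generalist; below the lower:
#' specialist; otherwise neutral. Taxa occupying a single sample with total
#' count below `min_count` are neutral by convention and flagged low-power.
#'
#' @param table feature table (taxa x samples), >= 5 samples.
#' @param n_perm permutations per taxon.
#' @param alpha two-tailed significance level.
#' @param min_count minimum total count for classification.
#' @param seed integer seed.
#' @return data.frame: taxon, B, null_lo, null_hi, label, low_power.
#' @export
classify_niche <- function(table, n_perm = 1000, alpha = 0.05, min_count = 10,
                           seed = NULL) {
  if (ncol(table) < 5) stopf("need >= 5 samples")
  keep <- rowSums(table) > 0
  tab <- table[keep, , drop = FALSE]
  depths <- colSums(tab)
  pdep <- depths / sum(depths)
  bd <- levins_b(tab)
  with_seed(seed, {
    res <- lapply(seq_len(nrow(tab)), function(i) {
      total <- sum(tab[i, ])
      obs <- bd$B[i]
      low_power <- bd$n_occupied[i] < 2 && total < min_count
      draws <- stats::rmultinom(n_perm, total, pdep)
      Pn <- sweep(draws, 2, colSums(draws), "/")
      nullB <- 1 / colSums(Pn^2)
      lo <- stats::quantile(nullB, alpha / 2, names = FALSE)
      hi <- stats::quantile(nullB, 1 - alpha / 2, names = FALSE)
      label <- if (low_power) "neutral"
        else if (obs > hi) "generalist"
        else if (obs < lo) "specialist"
        else "neutral"
      data.frame(taxon = bd$taxon[i], B = obs, null_lo = lo, null_hi = hi,
                 label = label, low_power = low_power,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
    out$label <- factor(out$label, c("generalist", "specialist", "neutral"))
    out
  })
}
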