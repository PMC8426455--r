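# Synthetic communities with known assembly processes. A regional pool with
# lognormal abundances lives on a simulated ultrametric phylogeny; local
# communities are assembled under one of five processes (drift, homogeneous /
# heterogeneous selection, dispersal limitation, homogenizing dispersal).
# Selection acts as Gaussian environmental filtering on a Brownian-evolved
# niche optimum, so that selection is phylogenetically structured and
# detectable by phylogenetic null models.

PROCESSES <- c("drift", "homogeneous_selection", "heterogeneous_selection",
               "dispersal_limitation", "homogenizing_dispersal")

#' Simulate an ultrametric pure-birth phylogeny
#'
#' Tip labels are "T0001", ...; total root-to-tip depth is rescaled to 1 so
#' phylogenetic distances are comparable across simulations.
#'
#' @param n_tips number of tips (>= 3).
#' @param seed integer seed.
#' @return a rooted ultrametric `phylo`.
#' @export
simulate_tree <- function(n_tips, seed = NULL) {
  if (n_tips < 3) stopf("n_tips must be >= 3")
  with_seed(seed, {
    tr <- ape::rphylo(n_tips, birth = 1, death = 0)
    depth <- max(ape::node.depth.edgelength(tr))
    tr$edge.length <- tr$edge.length / depth
    tr$tip.label <- sprintf("T%04d", seq_len(n_tips))
    tr
  })
}

#' Simulate a regional species pool on a tree
#'
#' Relative abundances are i.i.d. lognormal (then normalized); each taxon
#' carries a niche optimum evolved by Brownian motion along the tree
#' (variance proportional to branch length), used by the selection scenarios.
#'
#' @param tree phylo from [simulate_tree()].
#' @param lognormal_sigma sd of log abundance (> 0).
#' @param bm_sigma Brownian rate for the niche optimum.
#' @param seed integer seed.
#' @return list with `taxon_ids`, `abundance` (sums to 1) and `optimum`.
#' @export
simulate_pool <- function(tree, lognormal_sigma = 1, bm_sigma = 1, seed = NULL) {
  if (lognormal_sigma <= 0) stopf("lognormal_sigma must be > 0")
  with_seed(seed, {
    ab <- stats::rlnorm(length(tree$tip.label), meanlog = 0, sdlog = lognormal_sigma)
    ab <- ab / sum(ab)
    opt <- ape::rTraitCont(tree, model = "BM", sigma = bm_sigma)
    list(taxon_ids = tree$tip.label,
         abundance = stats::setNames(ab, tree$tip.label),
         optimum = stats::setNames(as.numeric(opt[tree$tip.label]), tree$tip.label))
  })
}

#' Scenario specification for community assembly
#'
#' @param process one of drift, homogeneous_selection, heterogeneous_selection,
#'   dispersal_limitation, homogenizing_dispersal.
#' @param n_samples number of local communities.
#' @param depth reads per community (>= 10).
#' @param sigma Gaussian filter width for the selection scenarios, in units of
#'   the Brownian niche-optimum scale.
#' @param m immigration rate from the pool per individual for the
#'   dispersal-limitation chain (small m = strong limitation).
#' @param generations drift resampling generations between adjacent samples in
#'   the dispersal-limitation chain (amplifies along-chain divergence).
#' @param seed integer seed.
#' @export
scenario_spec <- function(process, n_samples = 12, depth = 2000, sigma = 0.5,
                          m = 0.05, generations = 10, seed = NULL) {
  process <- match.arg(process, PROCESSES)
  if (n_samples < 2) stopf("n_samples must be >= 2")
  if (depth < 10) stopf("depth must be >= 10")
  if (sigma <= 0 || m < 0 || m > 1 || generations < 1)
    stopf("invalid scenario parameters")
  structure(list(process = process, n_samples = n_samples, depth = depth,
                 sigma = sigma, m = m, generations = generations, seed = seed),
            class = "scenario_spec")
}

#' Assemble local communities under a known ecological process
#'
#' * drift: each sample is an independent multinomial draw from the pool.
#' * homogeneous_selection: all samples share one environment `e*`; sampling
#'   weights are pool abundance times `exp(-(opt - e*)^2 / (2 sigma^2))`.
#' * heterogeneous_selection: as above but each sample draws its own `e*`
#'   uniformly over the range of the pool optima.
#' * dispersal_limitation: samples form a serial immigration chain; each
#'   sample is resampled from the previous local community (probability
#'   `1 - m` per individual) or the pool (probability `m`), with `generations`
#'   rounds of multinomial drift between adjacent samples.
#' * homogenizing_dispersal: one local community is realized from the pool
#'   through a finite founding population (depth/10 individuals) and every
#'   sample is a multinomial resample of it (mass-effects analogue).
#'
#' @param pool from [simulate_pool()].
#' @param tree tree the pool lives on (taxa order reference).
#' @param spec a [scenario_spec()].
#' @return list(table, metadata, truth) — table is taxa x samples with column
#'   sums exactly `spec$depth`; metadata labels all samples with compartment
#'   "bulk" and treatment "control"; truth records the generating process.
#' @export
assemble_communities <- function(pool, tree, spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  n <- length(pool$abundance)
  p <- as.numeric(pool$abundance)
  opt <- as.numeric(pool$optimum)
  S <- spec$n_samples
  with_seed(spec$seed, {
    draw <- function(w) as.numeric(stats::rmultinom(1, spec$depth, w))
    counts <- switch(spec$process,
      drift = vapply(seq_len(S), function(i) draw(p), numeric(n)),
      homogeneous_selection = {
        e <- stats::runif(1, stats::quantile(opt, 0.25), stats::quantile(opt, 0.75))
        w <- p * exp(-(opt - e)^2 / (2 * spec$sigma^2))
        vapply(seq_len(S), function(i) draw(w), numeric(n))
      },
      heterogeneous_selection = {
        es <- stats::runif(S, min(opt), max(opt))
        vapply(seq_len(S), function(i) {
          draw(p * exp(-(opt - es[i])^2 / (2 * spec$sigma^2)))
        }, numeric(n))
      },
      dispersal_limitation = {
        out <- matrix(0, n, S)
        local <- draw(p)
        out[, 1] <- local
        for (k in 2:S) {
          f <- local / sum(local)
          for (g in seq_len(spec$generations)) {
            w <- (1 - spec$m) * f + spec$m * p
            f <- draw(w) / spec$depth
          }
          local <- draw((1 - spec$m) * f + spec$m * p)
          out[, k] <- local
        }
        out
      },
      homogenizing_dispersal = {
        # the shared local community passes through a finite founding
        # population, so mass effects propagate one concentrated realization
        founders <- as.numeric(stats::rmultinom(1, max(10, round(spec$depth / 10)), p))
        f <- founders / sum(founders)
        vapply(seq_len(S), function(i) draw(f), numeric(n))
      })
    rownames(counts) <- pool$taxon_ids
    colnames(counts) <- sprintf("S%02d", seq_len(S))
    md <- sample_metadata(colnames(counts),
                          rep("bulk", S), rep("control", S))
    list(table = counts, metadata = md,
         truth = list(process = spec$process, n_samples = S,
                      depth = spec$depth, sigma = spec$sigma, m = spec$m,
                      generations = spec$generations, seed = spec$seed))
  })
}

#' Simulate a binary trait on a tree
#'
#' `brownian_threshold` evolves a continuous Brownian character and marks the
#' top `prevalence` fraction of tips positive (phylogenetically conserved);
#' `random` marks a uniform random subset positive.
#'
#' @param tree phylo.
#' @param model "brownian_threshold" or "random".
#' @param prevalence fraction of positive tips in (0, 1).
#' @param seed integer seed.
#' @return named 0/1 integer vector over tips; exactly
#'   `ceiling(prevalence * n)` positives.
#' @export
simulate_binary_trait <- function(tree, model = c("brownian_threshold", "random"),
                                  prevalence = 0.25, seed = NULL) {
  model <- match.arg(model)
  if (prevalence <= 0 || prevalence >= 1) stopf("prevalence must be in (0, 1)")
  n <- length(tree$tip.label)
  k <- ceiling(prevalence * n)
  with_seed(seed, {
    pos <- if (model == "random") {
      sample(tree$tip.label, k)
    } else {
      x <- ape::rTraitCont(tree, model = "BM", sigma = 1)
      names(sort(x, decreasing = TRUE))[seq_len(k)]
    }
    out <- stats::setNames(integer(n), tree$tip.label)
    out[pos] <- 1L
    out
  })
}

#' Apply a clade- or taxon-targeted treatment effect
#'
#' Expected counts of the target taxa are multiplied by `2^log2_effect`; each
#' sample is then resampled to its original depth by a multinomial draw, which
#' renormalizes the non-target expectations. Column sums are preserved
#' exactly.
#'
#' @param table feature table (taxa x samples).
#' @param target_taxa taxa receiving the effect (must exist in the table).
#' @param log2_effect log2 fold change applied to target expected counts. May
#'   be a single value or one value per sample (heterogeneous perturbation).
#' @param seed integer seed.
#' @return perturbed feature table with identical dimensions and column sums.
#' @export
apply_treatment_effect <- function(table, target_taxa, log2_effect, seed = NULL) {
  unknown <- setdiff(target_taxa, rownames(table))
  if (length(unknown))
    stopf("unknown target taxa: %s", paste(utils::head(unknown, 5), collapse = ", "))
  S <- ncol(table)
  eff <- rep_len(log2_effect, S)
  with_seed(seed, {
    out <- table
    tgt <- rownames(table) %in% target_taxa
    for (j in seq_len(S)) {
      w <- table[, j]
      if (sum(w) == 0) next
      w[tgt] <- w[tgt] * 2^eff[j]
      out[, j] <- as.numeric(stats::rmultinom(1, sum(table[, j]), w))
    }
    out
  })
}

#' Write a synthetic input bundle to disk
#'
#' Emits the same TSV/Newick formats the readers consume plus a `truth.json`
#' sidecar recording the scenario parameters and ground-truth process label.
#'
#' @param dir output directory (created if needed).
#' @param spec a [scenario_spec()].
#' @param n_tips tips in the simulated tree.
#' @param lognormal_sigma pool abundance sd (log scale).
#' @return invisible list of written paths.
#' @export
simulate_bundle <- function(dir, spec, n_tips = 150, lognormal_sigma = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tree <- simulate_tree(n_tips, seed = derive_seed(spec$seed, 1))
  pool <- simulate_pool(tree, lognormal_sigma, seed = derive_seed(spec$seed, 2))
  com <- assemble_communities(pool, tree, spec)
  paths <- list(table = file.path(dir, "table.tsv"),
                tree = file.path(dir, "tree.nwk"),
                metadata = file.path(dir, "metadata.tsv"),
                truth = file.path(dir, "truth.json"))
  write_feature_table(com$table, paths$table)
  ape::write.tree(tree, paths$tree)
  md <- data.frame("#SampleID" = rownames(com$metadata),
                   compartment = as.character(com$metadata$compartment),
                   treatment = as.character(com$metadata$treatment),
                   check.names = FALSE)
  utils::write.table(md, paths$metadata, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(com$truth, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
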