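# End-to-end orchestration: per compartment, run diversity -> responder
# classification -> co-occurrence networks (control vs drought) -> phylogenetic
# null models -> assembly partition -> niche breadth -> phylogenetic signal ->
# RAD fits, writing plain TSV/JSON artifacts plus a manifest. Per-stage seeds
# are derived deterministically from the master seed so any stage can be
# re-run standalone.

#' Assemble a pipeline configuration
#'
#' @param table,tree,metadata loaded inputs (see [read_feature_table()],
#'   [read_tree()], [read_sample_metadata()]); tree may be NULL to skip
#'   phylogenetic stages.
#' @param taxonomy optional taxonomy data.frame.
#' @param outdir output directory, or NULL to skip writing files.
#' @param seed master seed; per-stage seeds are derived from it.
#' @param n_null null-model randomizations.
#' @param params named list overriding stage defaults (fc_cutoff, r_min,
#'   p_max, min_prevalence, ds, n_min, niche_n_perm, signal_n_perm,
#'   partition_by_treatment).
#' @export
pipeline_config <- function(table, tree = NULL, metadata, taxonomy = NULL,
                            outdir = NULL, seed = 1, n_null = 999,
                            params = list()) {
  defaults <- list(fc_cutoff = 1.2, r_min = 0.6, p_max = 0.05,
                   min_prevalence = 0.5, ds = 0.2, n_min = 24,
                   niche_n_perm = 1000, signal_n_perm = 1000,
                   partition_by_treatment = TRUE)
  defaults[names(params)] <- params
  structure(list(table = table, tree = tree, metadata = metadata,
                 taxonomy = taxonomy, outdir = outdir, seed = seed,
                 n_null = n_null, params = defaults),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' @param config a [pipeline_config()].
#' @return nested list of per-compartment results plus a manifest describing
#'   every artifact and the parameters used.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  h <- harmonize(config$table, config$tree, config$metadata)
  tab <- h$table; md <- h$metadata; tree <- h$tree
  p <- config$params
  outdir <- config$outdir
  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed, n_null = config$n_null, params = p,
                   artifacts = character(0))
  emit <- function(obj, name, writer) {
    if (is.null(outdir)) return(invisible(NULL))
    path <- file.path(outdir, name)
    writer(obj, path)
    manifest$artifacts <<- c(manifest$artifacts, name)
  }
  tsv <- function(obj, path) utils::write.table(obj, path, sep = "\t",
                                                quote = FALSE, row.names = FALSE)
  mat_tsv <- function(obj, path) utils::write.table(
    data.frame(id = rownames(obj), obj, check.names = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  dcache <- if (!is.null(tree))
    patristic_distances(ape::keep.tip(tree, intersect(tree$tip.label, rownames(tab))))
  results <- list()
  for (comp in levels(droplevels(md$compartment))) {
    samples <- rownames(md)[md$compartment == comp]
    sub <- tab[, samples, drop = FALSE]
    sub <- sub[rowSums(sub) > 0, , drop = FALSE]
    smd <- md[samples, , drop = FALSE]
    res <- list()

    res$alpha <- list(
      shannon = alpha_diversity(sub, "shannon"),
      observed = alpha_diversity(sub, "observed_features"))
    if (!is.null(tree)) res$alpha$faith_pd <- alpha_diversity(sub, "faith_pd", tree)
    res$beta <- list(bray = beta_diversity(sub, "bray_curtis"))
    if (!is.null(tree)) res$beta$wuf <- beta_diversity(sub, "weighted_unifrac", tree)
    dm <- res$beta$wuf %||% res$beta$bray
    res$pcoa <- pcoa(dm, k = min(2, ncol(sub) - 1))
    both_trt <- all(table(smd$treatment) >= 2) && nlevels(droplevels(smd$treatment)) == 2
    if (both_trt) {
      res$permanova <- permanova(dm, smd$treatment, n_perm = config$n_null,
                                 seed = derive_seed(config$seed, 11))
      res$alpha_test <- compare_groups(res$alpha$shannon, smd$treatment)
      res$responders <- classify_responders(
        taxon_fold_changes(sub, smd), cutoff = p$fc_cutoff)
      emit(res$responders, paste0(comp, "_responders.tsv"), tsv)
      for (trt in c("control", "drought")) {
        keep <- smd$treatment == trt
        if (sum(keep) >= 5) {
          net <- build_network(sub[, keep, drop = FALSE], r_min = p$r_min,
                               p_max = p$p_max, min_prevalence = p$min_prevalence)
          res$network[[trt]] <- network_topology(net)
          res$hubs[[trt]] <- hub_scores(net)
        }
      }
      if (!is.null(res$network$control) && !is.null(res$network$drought))
        res$response_ratios <- response_ratios(res$network$drought,
                                               res$network$control)
      if (!is.null(tree)) {
        for (dir in c("positive", "negative")) {
          trait <- responder_trait(res$responders, dir)
          if (sum(trait) >= 2 && sum(trait) < length(trait)) {
            tr_sub <- ape::keep.tip(tree, names(trait))
            res$signal[[dir]] <- c(
              fritz_purvis_d(tr_sub, trait, n_perm = p$signal_n_perm,
                             seed = derive_seed(config$seed, 31)),
              consentrait(tr_sub, trait)[c("tau_d")])
          }
        }
      }
    }
    if (!is.null(tree)) {
      res$ses_mntd <- ses_phylo(sub, dcache, "mntd", n_null = config$n_null,
                                seed = derive_seed(config$seed, 21))
      emit(res$ses_mntd, paste0(comp, "_ses_mntd.tsv"), tsv)
      groups <- if (p$partition_by_treatment && both_trt)
        split(samples, smd$treatment) else list(all = samples)
      for (gname in names(groups)) {
        gs <- groups[[gname]]
        if (length(gs) < 3) next
        gtab <- sub[, gs, drop = FALSE]
        gtab <- gtab[rowSums(gtab) > 0, , drop = FALSE]
        res$assembly[[gname]] <- icamp_partition(
          gtab, tree, n_null = config$n_null, ds = p$ds, n_min = p$n_min,
          seed = derive_seed(config$seed, 41))
      }
    }
    res$niche <- classify_niche(sub, n_perm = p$niche_n_perm,
                                seed = derive_seed(config$seed, 51))
    res$bcom <- community_bcom(sub)
    emit(res$niche, paste0(comp, "_niche.tsv"), tsv)
    res$rad <- lapply(stats::setNames(colnames(sub), colnames(sub)),
                      function(s) {
                        x <- sub[, s]
                        if (sum(x > 0) < 4) return(NULL)
                        compare_rads(x)
                      })
    emit(dm, paste0(comp, "_distance.tsv"), mat_tsv)
    results[[comp]] <- res
  }
  if (!is.null(outdir)) {
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(results = results, manifest = manifest)
}
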