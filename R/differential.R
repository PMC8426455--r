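# Fold-change based classification of treatment-responsive taxa. Counts are
# converted to relative abundances per sample, optionally aggregated to a
# taxonomic rank, and compared between treatments by log2 fold change of
# group means with a Wilcoxon rank-sum test and BH-FDR across taxa.

#' Per-taxon fold-change statistics between treatments
#'
#' log2FC = log2((mean_drought + eps) / (mean_control + eps)) on per-sample
#' relative abundances; eps defaults to half the smallest nonzero relative
#' abundance in the analyzed table, applied symmetrically so sign is
#' preserved. Taxa absent from both groups are excluded.
#'
#' @param table feature table (taxa x samples).
#' @param metadata metadata data.frame (rownames = samples) with a
#'   `treatment` column (control/drought).
#' @param rank "asv" or one of phylum, class, order, family, genus (requires
#'   `taxonomy`).
#' @param taxonomy data.frame from [read_taxonomy()].
#' @param summary_fun group summary statistic ("mean" or "median").
#' @return data.frame: taxon, mean_control, mean_drought, log2FC, log10FC,
#'   p (Wilcoxon rank-sum, two-sided), q (BH-FDR at this rank).
#' @export
taxon_fold_changes <- function(table, metadata, rank = "asv", taxonomy = NULL,
                               summary_fun = c("mean", "median")) {
  summary_fun <- match.arg(summary_fun)
  metadata <- metadata[colnames(table), , drop = FALSE]
  trt <- as.character(metadata$treatment)
  if (!all(c("control", "drought") %in% trt))
    stopf("both treatments must be present")
  rel <- sweep(table, 2, colSums(table), "/")
  if (rank != "asv") {
    if (is.null(taxonomy)) stopf("rank '%s' requires a taxonomy", rank)
    if (!rank %in% names(taxonomy)) stopf("unknown rank '%s'", rank)
    lineage <- taxonomy[[rank]][match(rownames(rel), taxonomy$taxon_id)]
    lineage[is.na(lineage)] <- "unclassified"
    rel <- rowsum(rel, group = lineage)
  }
  keep <- rowSums(rel) > 0
  rel <- rel[keep, , drop = FALSE]
  eps <- min(rel[rel > 0]) / 2
  ctl <- rel[, trt == "control", drop = FALSE]
  dro <- rel[, trt == "drought", drop = FALSE]
  fun <- if (summary_fun == "mean") rowMeans else function(m) apply(m, 1, stats::median)
  m_c <- fun(ctl)
  m_d <- fun(dro)
  log2fc <- log2((m_d + eps) / (m_c + eps))
  p <- vapply(seq_len(nrow(rel)), function(i) {
    if (all(rel[i, ] == rel[i, 1])) return(1)
    suppressWarnings(stats::wilcox.test(dro[i, ], ctl[i, ], exact = FALSE)$p.value)
  }, numeric(1))
  data.frame(taxon = rownames(rel), rank = rank,
             mean_control = m_c, mean_drought = m_d,
             log2FC = log2fc, log10FC = log2fc * log10(2),
             p = p, q = stats::p.adjust(p, "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify taxa as treatment-positive, -negative or neutral
#'
#' A taxon is positive when log2FC > cutoff (and q <= alpha when
#' `require_significance`), negative symmetrically, neutral otherwise. The
#' default cutoff of 1.2 log2 units reproduces the |log2FC| > 1.2 responder
#' rule commonly used for drought-responsive ASVs.
#'
#' @param stats data.frame from [taxon_fold_changes()].
#' @param cutoff positive log2FC threshold.
#' @param alpha FDR level when significance is required.
#' @param require_significance also require q <= alpha.
#' @return the input with a `label` column plus a "counts" attribute.
#' @export
classify_responders <- function(stats, cutoff = 1.2, alpha = 0.05,
                                require_significance = FALSE) {
  if (cutoff <= 0) stopf("cutoff must be > 0")
  sig <- if (require_significance) stats$q <= alpha else TRUE
  label <- ifelse(stats$log2FC > cutoff & sig, "positive",
                  ifelse(stats$log2FC < -cutoff & sig, "negative", "neutral"))
  stats$label <- factor(label, c("positive", "negative", "neutral"))
  attr(stats, "counts") <- table(stats$label)
  stats
}

#' Export a responder trait vector for phylogenetic-signal analysis
#'
#' @param classified output of [classify_responders()].
#' @param direction "positive" or "negative": which label becomes trait 1.
#' @return named 0/1 vector over taxa.
#' @export
responder_trait <- function(classified, direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  stats::setNames(as.integer(classified$label == direction), classified$taxon)
}
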