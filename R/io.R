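# Reading, validation and harmonization of the three standard inputs:
# an ASV-by-sample count table (TSV), sample metadata (TSV) and a rooted
# phylogeny (Newick). The table convention throughout the package is
# taxa in rows, samples in columns.

COMPARTMENTS <- c("leaf", "stem", "root", "rhizosphere", "bulk")
TREATMENTS <- c("control", "drought")

#' Validate a feature table
#'
#' A feature table is an integer matrix of counts with taxa as rows and
#' samples as columns, both uniquely named. All-zero samples are allowed at
#' this stage (they are flagged and dropped at [harmonize()]).
#'
#' @param counts numeric matrix, taxa x samples.
#' @return the validated matrix (invisibly classed `feature_table`).
#' @export
feature_table <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stopf("feature table needs taxon row names and sample column names")
  if (anyDuplicated(rownames(counts)))
    stopf("duplicated taxon id(s): %s",
          paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stopf("duplicated sample id(s): %s",
          paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (!is.numeric(counts) || any(is.na(counts)))
    stopf("feature table must be numeric with no missing values")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stopf("negative count at taxon '%s', sample '%s'",
          rownames(counts)[bad[1]], colnames(counts)[bad[2]])
  }
  if (any(counts != round(counts)))
    stopf("feature table must contain integer counts")
  storage.mode(counts) <- "double"
  empty <- colSums(counts) == 0
  if (any(empty))
    warnf("sample(s) with zero total count flagged for exclusion: %s",
          paste(colnames(counts)[empty], collapse = ", "))
  class(counts) <- c("feature_table", class(counts))
  counts
}

#' Read a feature table from TSV
#'
#' First column holds taxon ids, header row holds sample ids, cells are
#' non-negative integer counts.
#'
#' @param path path to a tab-separated file.
#' @return a taxa x samples count matrix (see [feature_table()]).
#' @export
read_feature_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  if (ncol(df) < 2) stopf("feature table '%s' has no sample columns", path)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(m, 2, as.numeric))), arr.ind = TRUE)
    if (length(bad)) {
      stopf("non-numeric cell at row %d, column '%s'",
            bad[1, 1], colnames(m)[bad[1, 2]])
    }
    storage.mode(m) <- "double"
  }
  rownames(m) <- ids
  feature_table(m)
}

#' Write a feature table as TSV (taxa rows, sample columns)
#' @param table feature table matrix.
#' @param path output path.
#' @param id_column name of the leading id column.
#' @export
write_feature_table <- function(table, path, id_column = "#ASV_ID") {
  df <- data.frame(id = rownames(table), table, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' Expects columns `#SampleID`, `compartment` (leaf, stem, root, rhizosphere,
#' bulk) and `treatment` (control, drought).
#'
#' @param path path to a tab-separated metadata file.
#' @return data.frame with rownames = sample ids and columns
#'   `compartment`, `treatment` (factors with closed level sets).
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  names(df)[1] <- sub("^#", "", names(df)[1])
  need <- c("SampleID", "compartment", "treatment")
  if (!all(need %in% names(df)))
    stopf("metadata must have columns #SampleID, compartment, treatment")
  sample_metadata(df$SampleID, df$compartment, df$treatment)
}

#' Construct validated sample metadata
#' @param sample_id character vector of unique sample ids.
#' @param compartment one of leaf, stem, root, rhizosphere, bulk per sample.
#' @param treatment one of control, drought per sample.
#' @export
sample_metadata <- function(sample_id, compartment, treatment) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) stopf("duplicated sample id in metadata")
  compartment <- as.character(compartment)
  treatment <- as.character(treatment)
  if (!all(compartment %in% COMPARTMENTS))
    stopf("unknown compartment(s): %s",
          paste(setdiff(compartment, COMPARTMENTS), collapse = ", "))
  if (!all(treatment %in% TREATMENTS))
    stopf("unknown treatment(s): %s",
          paste(setdiff(treatment, TREATMENTS), collapse = ", "))
  out <- data.frame(compartment = factor(compartment, COMPARTMENTS),
                    treatment = factor(treatment, TREATMENTS),
                    row.names = sample_id, stringsAsFactors = FALSE)
  out
}

#' Read a rooted phylogeny from Newick
#'
#' Unrooted trees are midpoint-rooted with a warning; every edge must carry a
#' branch length (zero allowed).
#'
#' @param path Newick file.
#' @return an [ape] `phylo` object, rooted, with branch lengths.
#' @export
read_tree <- function(path) {
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stopf("cannot parse Newick in '%s': %s",
                                           path, conditionMessage(e)))
  if (is.null(tr)) stopf("cannot parse Newick in '%s'", path)
  validate_tree(tr)
}

#' @rdname read_tree
#' @param tree a `phylo` object to validate in place of a file.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stopf("not a phylo object")
  if (is.null(tree$edge.length) || length(tree$edge.length) != nrow(tree$edge)) {
    miss <- if (is.null(tree$edge.length)) seq_len(nrow(tree$edge)) else
      which(is.na(tree$edge.length))
    stopf("tree is missing branch lengths on edge(s): %s",
          paste(utils::head(miss, 10), collapse = ", "))
  }
  if (any(is.na(tree$edge.length)))
    stopf("tree is missing branch lengths on edge(s): %s",
          paste(which(is.na(tree$edge.length)), collapse = ", "))
  if (any(tree$edge.length < 0)) stopf("negative branch length in tree")
  if (anyDuplicated(tree$tip.label)) stopf("duplicated tip labels in tree")
  if (!ape::is.rooted(tree)) {
    warnf("input tree is unrooted; midpoint-rooting it")
    tree <- phangorn::midpoint(tree)
  }
  tree
}

#' Read a Greengenes-style taxonomy TSV
#'
#' Two columns: taxon id and a `k__...; p__...; c__...` lineage string.
#' Missing ranks are returned as NA.
#'
#' @param path taxonomy TSV.
#' @return data.frame with columns taxon_id, kingdom, phylum, class, order,
#'   family, genus.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  ranks <- c(k = "kingdom", p = "phylum", c = "class", o = "order",
             f = "family", g = "genus")
  parse_one <- function(s) {
    parts <- trimws(strsplit(s, ";")[[1]])
    out <- stats::setNames(rep(NA_character_, length(ranks)), ranks)
    for (p in parts) {
      m <- regmatches(p, regexec("^([kpcofg])__(.*)$", p))[[1]]
      if (length(m) == 3 && nzchar(m[3])) out[ranks[m[2]]] <- m[3]
    }
    out
  }
  lin <- t(vapply(df[[2]], parse_one, character(length(ranks))))
  rownames(lin) <- NULL
  data.frame(taxon_id = as.character(df[[1]]), lin, stringsAsFactors = FALSE)
}

#' Harmonize a feature table, tree and metadata
#'
#' Restricts the table to samples present in the metadata (warning lists any
#' dropped), drops all-zero samples with a warning, and errors if any table
#' taxon is missing from the tree tips. The tree is returned unpruned: pool
#' definitions for null models happen downstream.
#'
#' @param table feature table (taxa x samples).
#' @param tree rooted `phylo`, or NULL to skip the tip check.
#' @param metadata data.frame as from [read_sample_metadata()].
#' @return list(table, tree, metadata) restricted to the common samples.
#' @export
harmonize <- function(table, tree = NULL, metadata) {
  keep <- intersect(colnames(table), rownames(metadata))
  if (length(keep) == 0) stopf("no samples shared between table and metadata")
  dropped <- setdiff(colnames(table), keep)
  if (length(dropped))
    warnf("dropping sample(s) without metadata: %s", paste(dropped, collapse = ", "))
  tab <- table[, keep, drop = FALSE]
  zero <- colSums(tab) == 0
  if (any(zero)) {
    warnf("dropping zero-count sample(s): %s",
          paste(colnames(tab)[zero], collapse = ", "))
    tab <- tab[, !zero, drop = FALSE]
  }
  if (!is.null(tree)) {
    missing_tips <- setdiff(rownames(tab), tree$tip.label)
    if (length(missing_tips))
      stopf("taxa absent from tree tips: %s",
            paste(utils::head(missing_tips, 10), collapse = ", "))
  }
  list(table = tab, tree = tree,
       metadata = metadata[colnames(tab), , drop = FALSE])
}

#' Rarefy a feature table to even depth
#'
#' Subsamples each sample without replacement to `depth` reads. Samples whose
#' total is below `depth` are dropped with a warning.
#'
#' @param table feature table (taxa x samples).
#' @param depth target reads per sample (default: minimum column sum).
#' @param seed integer seed for reproducibility.
#' @return rarefied feature table; every retained column sums to `depth`.
#' @export
rarefy_table <- function(table, depth = min(colSums(table)), seed = NULL) {
  if (depth <= 0) stopf("rarefaction depth must be positive")
  totals <- colSums(table)
  low <- totals < depth
  if (any(low)) {
    warnf("dropping sample(s) below depth %d: %s", depth,
          paste(colnames(table)[low], collapse = ", "))
    table <- table[, !low, drop = FALSE]
    totals <- totals[!low]
  }
  with_seed(seed, {
    out <- table
    for (j in seq_len(ncol(table))) {
      x <- table[, j]
      if (totals[j] == depth) next
      picked <- sample.int(totals[j], depth)
      # map sampled read indices back to taxa via cumulative counts
      out[, j] <- tabulate(findInterval(picked - 1L, cumsum(x), left.open = FALSE) + 1L,
                           nbins = nrow(table))
    }
    out
  })
}
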