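Package: campr
Title: Community Assembly and Phylogenetic Null Models for Plant Microbiomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring the ecological processes that structure
    plant-associated microbial communities from amplicon feature tables, a
    rooted phylogeny and sample metadata. Implements alpha/beta diversity and
    ordination (Shannon, Faith's PD, Bray-Curtis, normalized weighted UniFrac,
    PCoA, PERMANOVA), fold-change based classification of treatment-responsive
    taxa, Spearman co-occurrence networks with topology and hub statistics,
    phylogenetic null models (SES-MPD/MNTD, betaNTI), a Bray-Curtis Raup-Crick
    null model, the two-stage betaNTI + RC decision rule and a phylogenetic
    bin-based five-process partition of community turnover (heterogeneous and
    homogeneous selection, dispersal limitation, homogenizing dispersal,
    drift), Levins' niche breadth with a permutation-based
    generalist/specialist classifier, phylogenetic signal of binary traits
    (Fritz-Purvis D and consenTRAIT trait depth), and rank-abundance model
    comparison by AIC. Includes a synthetic-community simulator with known
    assembly processes for validating every stage against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    vegan,
    picante,
    phangorn,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    phyloseq
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
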