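---
title: "Inferring community assembly processes with campr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring community assembly processes with campr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(campr)
```

# The question the package answers

Plant-associated microbial communities (for example the leaf, stem, root,
rhizosphere and bulk-soil compartments of wild rice) respond to stresses such
as drought both in *which* taxa they contain and in *how* those taxa are
assembled. campr implements the full inference stack used in this style of
study: diversity and ordination, classification of treatment-responsive taxa,
co-occurrence network stability, phylogenetic null models, a five-process
partition of community turnover, niche-breadth analysis, phylogenetic signal
of a binary response trait, and rank-abundance model selection. Every stage
can be exercised on synthetic communities with known ground truth, so the
statistical behaviour of the whole pipeline is testable.

Inputs are an ASV-by-sample count table (taxa in rows), sample metadata
(compartment and treatment), and a rooted phylogeny with branch lengths whose
tips cover the table's taxa. The tree is deliberately *not* pruned to the
observed taxa at load time: several null models below define their species
pool from it.

# Models and statistics

## Diversity and ordination

Shannon diversity is reported in bits (log base 2), matching the QIIME2
convention, so four equally abundant taxa score exactly 2. Faith's PD
includes the path to the root (again the QIIME2 default). Weighted UniFrac is
the normalized variant
\(\sum_b \ell_b\,|p_b - q_b| \,/\, \sum_b \ell_b\,(p_b + q_b)\)
over branches \(b\) with length \(\ell_b\) and descendant relative abundances
\(p_b, q_b\), so it ranges over \([0, 1]\) and equals 1 when two one-taxon
samples sit on opposite sides of the root. PCoA reports negative eigenvalues
rather than correcting them; PERMANOVA uses label permutation with
\(p = (1 + \#\{F^\ast \ge F\}) / (1 + n_{perm})\); pairwise PERMANOVA applies
Benjamini–Hochberg correction (the multiplicity rule is stated here because
pairwise wrappers in the wild differ silently). Group comparisons of scalar
indices use tie-corrected Kruskal–Wallis tests; a constant vector returns
\(H = 0, p = 1\) by convention.

## Treatment-responsive taxa

Counts are converted to per-sample relative abundances, optionally aggregated
to a taxonomic rank, and summarized per treatment by the arithmetic mean
(median optional). The effect size is
\(\log_2((\bar{x}_{drought} + \varepsilon)/(\bar{x}_{control} + \varepsilon))\)
with \(\varepsilon\) equal to half the smallest nonzero relative abundance in
the analyzed table, applied to both groups so the sign is preserved and
presence/absence flips stay finite. Taxa with \(|\log_2 FC| > 1.2\) are
labelled positive/negative responders; a Wilcoxon rank-sum test with BH-FDR
can additionally be required (`require_significance = TRUE`), because the
fold-change-only rule and the significance-filtered rule are both in common
use and they answer slightly different questions.

## Co-occurrence networks

Networks connect taxa whose Spearman correlation satisfies \(|r| > 0.6\) and
\(p < 0.05\) (unadjusted by default; a BH mode exists). Taxa present in fewer
than half the samples are removed first — rank correlations on mostly-zero
vectors are spurious — and constant taxa are excluded because their rank
correlation is undefined. "Clusters" means connected components. Hub
(keystone) scores are the principal eigenvector of the adjacency matrix,
computed per component, scaled to a maximum of 1 within each component and
then weighted by the component's spectral radius relative to the largest, so
the dominant component's hub scores reach 1 and minor components are ranked
below it. Stability comparisons between treatments use response ratios
(treatment/control) of average degree, edge count, vertex count and cluster
count; a zero control value yields a flagged missing ratio.

## Phylogenetic null models

MPD and MNTD are computed from the dense patristic distance matrix
(capped at 5000 taxa to keep the \(O(n^2)\) memory contract explicit).
Standardized effect sizes shuffle taxon labels on the distance matrix
restricted to the species pool — the "taxa labels" scheme — and use the
sample standard deviation over null draws:
\(SES = (obs - \overline{null}) / sd(null)\), with \(NTI = -SES_{MNTD}\).
For very small pools an exhaustive mode enumerates every same-size subset, so
worked examples are exact rather than Monte Carlo. The α-level pool defaults
to the taxa observed in the analyzed group; βMNTD/βNTI are abundance-weighted
by default and include shared taxa at distance zero (the picante/Stegen
convention). A consequence worth stating: because a single permutation moves
both communities' taxa together, a pair of identical samples has zero
observed βMNTD *and* zero in every null draw, so its βNTI is undefined and is
flagged as such rather than reported as extreme.

## The five-process partition

Pairwise turnover is classified by the two-stage rule: βNTI > +2 means
heterogeneous selection, βNTI < −2 homogeneous selection; otherwise
RC\(_{Bray}\) > 0.95 means dispersal limitation, RC < −0.95 homogenizing
dispersal, and the remainder is drift. The Raup–Crick null fixes each
sample's richness, draws taxa with probability proportional to occupancy,
seeds each with one individual and fills to the observed total by pool
abundance weights; RC is the tie-corrected percentile of the observed
Bray–Curtis in the null distribution, rescaled to \([-1, 1]\).

The phylogenetic-bin variant (`icamp_partition()`) first partitions taxa into
clades whose within-clade patristic distance is at most `ds = 0.2` (in units
of the tree, which the simulator scales to unit depth), merging clades
smaller than `n_min = 24` with their phylogenetically nearest neighbour —
ties break toward the smaller neighbour. `n_min = 24` is the upstream
default of the binning framework; on 100–200-tip trees smaller bins
measurably destroy the power of the bin-restricted null models, so the
desk-scale default equals the field default. Both null models then run
within bins, and pair-level calls are aggregated with weights equal to the
mean relative abundance of the bin in the two samples (renormalized over the
bins usable for that pair). Two conventions matter:

* **Null universe.** By default the null shuffles taxa over *all tips of the
  supplied tree* (`pool = "tree"`), treating the tree as the regional pool.
  Restricting the universe to observed taxa (`pool = "table"`) makes
  environmental filtering invisible whenever sampling is deep enough that the
  observed pool *is* the filtered set.
* **Zero turnover.** A bin-pair whose observed βMNTD equals every null draw
  carries no phylogenetic information about selection; it falls through to
  the RC stage (βNTI treated as 0) instead of being discarded, so fully
  overlapping communities are still classified.

## Niche breadth

Levins' breadth for taxon \(j\) is \(B_j = 1/\sum_i P_{ij}^2\) with
\(P_{ij}\) the proportion of the taxon's individuals in sample \(i\)
(habitat unit = sample; the grouping key is configurable). The community
value Bcom is the unweighted mean of \(B\) over taxa occurring in a sample
(an abundance-weighted variant exists but is off by default). The
generalist/specialist classifier compares each taxon's observed \(B\) to a
permutation null that redistributes its total count across samples with
probabilities proportional to sample depths — the per-taxon marginal of
reshuffling all individuals while preserving per-sample totals — and labels
the taxon generalist above the \(1-\alpha/2\) null quantile, specialist below
the \(\alpha/2\) quantile (two-tailed \(\alpha = 0.05\), 1000 permutations by
default; this criterion is our implementation choice, stated openly because
the literature rarely pins it down). Single-sample taxa with fewer than 10
individuals are neutral by convention and flagged low-power.

## Phylogenetic signal

Fritz–Purvis \(D\) scores a binary trait by its sum of sister-clade
differences \(S\): internal node values are estimated by equal-weights
averaging of child values from the tips toward the root, and each node
contributes the mean absolute deviation between its children. \(D\) rescales
the observed \(S\) between two reference distributions obtained on the same
tree: tip-label shuffles (anchor 1, phylogenetically random) and Brownian
simulations thresholded to the observed prevalence (anchor 0,
Brownian-conserved); \(D < 0\) is stronger-than-Brownian clumping. Brownian
references threshold at \(\min(k, n-k)\) positives, which is
distribution-identical (Brownian motion is sign-symmetric) and makes \(D\)
exactly invariant to swapping the 0/1 labels. Both p-values are add-one
smoothed tail fractions. \(D\) ignores branch lengths entirely, so it is
invariant to rescaling the tree.

consenTRAIT's \(\tau_D\) is the mean depth of the maximal clades in which at
least 90% of tips carry the trait, where a clade's depth is the mean
patristic distance from its root node to its tips; positive tips outside any
qualifying clade contribute half their terminal branch length as singletons.
\(\tau_D\) therefore scales linearly with branch lengths. Clade abundance
weighting is not applied.

## Rank-abundance models

Four models are fitted to each sample's ranked counts by maximum Poisson
likelihood with a log link (delegated to the vegan fitting framework):
geometric-series preemption (1 parameter), broken stick (0), lognormal (2)
and Zipf–Mandelbrot (3); AIC \(= 2k - 2\log L\) with exactly those parameter
counts, which matters because the models are nested in spirit and AIC
comparisons are meaningless if \(k\) is inconsistent. The broken-stick
expectation \((N/S)\sum_{k=r}^{S} 1/k\) is also exposed in closed form for
communities too small to fit (< 4 taxa).

# The synthetic-data generator

The generator is first-class, tested code, not a fixture. A pure-birth
ultrametric tree (unit root-to-tip depth, tips `T0001…`) carries a regional
pool with i.i.d. lognormal relative abundances (`lognormal_sigma = 1`, a
moderately uneven pool typical of amplicon surveys) and a niche optimum
evolved by Brownian motion along the branches, so that selection on the
optimum is phylogenetically structured and visible to phylogenetic null
models. Local communities are assembled under one of five processes:

* **drift** — independent multinomials from the pool;
* **homogeneous selection** — one shared environment \(e^\ast\) (drawn from
  the interquartile range of the optima so the filter is never vacuously at
  the edge), Gaussian weights \(\propto\) pool \(\times
  \exp(-(opt - e^\ast)^2/2\sigma^2)\) with \(\sigma = 0.5\) on an optimum
  scale of roughly unit variance — strong but not cliff-like filtering;
* **heterogeneous selection** — the same filter, but each sample draws its
  own \(e^\ast\) uniformly over the full optima range;
* **dispersal limitation** — a serial immigration chain: between adjacent
  samples the local community passes through 10 generations of
  multinomial drift with per-generation immigration rate \(m = 0.05\) from
  the pool, producing distance decay along the chain (there is no explicit
  spatial coordinate, so no spatial-decay parameter exists);
* **homogenizing dispersal** — one shared local community realized through a
  finite founding population of depth/10 individuals, then resampled per
  sample; the founder bottleneck concentrates composition so that pairwise
  Bray–Curtis is reliably below drift's.

Depths default to 2000 reads over 12 samples, and tests use 100–200 tips —
scales at which every null model completes in seconds on one core. Treatment
effects multiply target taxa's expected counts by \(2^{\log_2 FC}\) and
resample each sample to its original depth, so column sums are conserved
exactly and the non-target share is renormalized (a +2 effect on a 1% taxon
realizes ≈ 4× before the small renormalization correction).

What the generator does *not* emulate: sequencing noise and chimeras,
compositional artefacts of unequal depths, taxon–taxon interactions,
time-series dynamics, and any correlation between abundance and niche
optimum. Passing tests therefore demonstrate statistical correctness of the
inference machinery under a known ecological model, not robustness to
amplicon-processing artefacts.

# Validation scale and honest limits of resolution

The test suite and the acceptance script validate the pipeline at desk scale:
150-tip trees, 12 samples, depth 2000, 127–239 null randomizations, 8–10
seeds per scenario, 30–50 replicate trees for trait-signal calibration, and
300 replicates for type-I rates. These sizes were chosen so the whole suite
runs in minutes; the statistics themselves accept the conventional 999
randomizations for production use.

Three limits of resolution are worth knowing, all measured by the
acceptance suite itself:

1. **Homogeneous selection vs homogenizing dispersal.** At depth 2000 with
   ≤ 200 taxa, replicate samples under a shared filter overlap almost
   completely. Conspecific-inclusive βMNTD scores shared taxa zero in the
   observation *and* in every null draw, so βNTI cannot reach −2 no matter
   how clustered the community is; such pairs carry an RC ≈ −1 signature
   instead and are classified as homogenizing dispersal or drift. An
   exclude-conspecifics variant was evaluated and rejected: it restores a
   weak homogeneous-selection signal but destroys the heterogeneous one.
   Distinguishing these two processes needs either much larger pools relative
   to depth (as in real surveys with 10⁴–10⁵ ASVs) or an α-level clustering
   statistic against the regional tree.
2. **Homogenizing dispersal per se.** The Raup–Crick pool is estimated from
   the analyzed samples; when all samples are resamples of one homogenized
   community, the null reproduces the observed process and RC stays at drift
   levels. Detecting homogenization requires a reference pool broader than
   the homogenized group.
3. **Raup–Crick calibration.** On neutral data the estimated pool's rare tail
   is biased upward (taxa are counted only if seen), making null communities
   systematically slightly more dissimilar than observed ones; with 12
   samples this costs roughly ten percentage points of nominal 95% coverage.
   A control experiment drawing nulls from the true generator pool calibrates
   exactly, isolating pool estimation as the cause. The canonical algorithm
   is retained; users should read |RC| near the 0.95 threshold with this
   conservatism in mind.

Bin-restricted Raup–Crick also loses power relative to the whole-community
statistic (a per-bin Bray–Curtis over ~30–50 taxa is noisy), so on
dispersal-limited chains the binned partition recovers the generating process
less often than the community-level two-stage rule does; when dispersal is
the hypothesis of interest, run `stegen_partition()` on `beta_nti()` +
`rc_bray()` alongside `icamp_partition()`.

# Numerical conventions and degenerate inputs

Ties in Spearman correlations use mid-ranks; edge p-values use the t
approximation on \(n-2\) degrees of freedom. RC ties count half, with a
\(10^{-12}\) tolerance for floating-point equality of Bray–Curtis values.
SES with a zero null standard deviation is flagged undefined, never ±Inf.
Empty samples are rejected by diversity functions and dropped with a warning
at harmonization; all-zero taxa are silently excluded from per-taxon
statistics. Rarefaction samples without replacement and preserves zeros.
Every stochastic function takes an explicit seed and restores the caller's
RNG state; the pipeline derives per-stage seeds from its master seed by a
fixed affine map modulo 2³¹−1, so stages are independently reproducible.

# Using the pipeline

```{r example, eval = FALSE}
dir <- tempfile()
simulate_bundle(dir, scenario_spec("drift", n_samples = 12, depth = 2000,
                                   seed = 1))
tab <- read_feature_table(file.path(dir, "table.tsv"))
tree <- read_tree(file.path(dir, "tree.nwk"))
md <- read_sample_metadata(file.path(dir, "metadata.tsv"))
cfg <- pipeline_config(tab, tree, md, outdir = file.path(dir, "out"),
                       seed = 1, n_null = 999)
res <- run_pipeline(cfg)
res$results$bulk$assembly$all$fractions
```
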