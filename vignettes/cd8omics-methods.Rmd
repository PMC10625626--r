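---
title: "Models and methods in cd8omics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in cd8omics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cd8omics)
library(dplyr)
```

This vignette is the package's account of the statistics and algorithms it
implements, the defaults it chooses where the underlying study is silent, and
what its synthetic-data tests do and do not demonstrate about real data.

## Label-free proteome quantification

An `intensity_matrix` holds proteins × samples MS intensities with an
explicit missing-value mask. Missingness is information (label-free data are
left-censored: low-abundance proteins drop out), so no function imputes;
values are masked at read time and stay masked.

**Normalization.** `median_normalize()` scales each sample so its median
present intensity equals the geometric mean of the per-sample medians —
equivalently, each sample's median log2 intensity is shifted to the common
value. This removes per-run loading differences and is deliberately
multiplicative so zeros and the mask are untouched. The factors are derived
from linear-scale medians because a median over an even number of values
averages two order statistics, and only the linear-scale construction makes
the post-condition ("per-sample medians equal, within 1e-9 relative") exact.
It is a local stand-in for vendor-side cross-run normalization; skip the
call to work on raw intensities. Note one practical consequence: the
synthetic generator plants per-sample loading scales, and unnormalized
two-group tests on such data are *conservative* (the shared scale inflates
within-group variance); calibration statements below assume the
normalize-then-test order the pipeline prescribes.

**Differential expression.** `differential_test()` runs a per-feature
two-sided two-sample Student t-test (pooled variance; Welch behind
`var_equal = FALSE`) on log2 intensities, with zeros treated as missing
before the transform. `log2fc` is mean(log2 knockout) − mean(log2 control).
Significance requires `p < alpha` *and* the fold change to clear a gate
(`log2fc > hi` or `log2fc < lo`); three presets mirror the study's printed
thresholds (`de_preset()`): proteome α = 0.05 with no gate; one RNA profile
at α = 0.001 with |log2FC| > 2; the other at α = 0.05 with log2FC > 0.20 —
an upper gate only, so that preset can never call downregulation. Features
with fewer than two quantified values in a group are reported untested and
are never significant. Zero-variance degeneracies keep the output total:
equal constants give p = 1, unequal constants the smallest representable
positive p with a `degenerate` flag (the t statistic is undefined; ranking
is preserved). Benjamini–Hochberg is the default correction, Bonferroni
available — the study uses both, in different figures.

**Proteomic ruler.** `proteomic_ruler()` converts intensity to absolute
copies per cell by `copies = I · N_A · m_DNA / (MW · Σ histone I)`. The
ruler's premise is that total histone mass ≈ DNA mass, so the summed histone
signal calibrates one cell's worth of signal. Copies are computed per sample
and averaged within group; the estimate is invariant to any uniform
rescaling of a sample's intensities (the scale cancels between numerator and
histone sum) and linear in `dna_mass_per_cell`. The default DNA mass,
5.89e-12 g, is the diploid mouse genome (2 × 2.73 Gbp × 650 g/mol/bp ÷ N_A);
it is a biological constant, not a tuning knob, and must be overridden for
other genomes or ploidies.

## Enrichment

**Over-representation.** `fisher_ora()` tests each gene set's overlap with
the DE features by Fisher's exact test on the 2×2 table over a declared
universe. The universe defaults to every feature detected in the experiment
— the proteomics convention; testing against a whole-genome universe
overstates enrichment when only a few thousand proteins were quantifiable.
The two-sided test is the default because that is what the study's legends
state; the one-tailed variant (`alternative = "greater"`, identical to the
hypergeometric upper tail) is exposed and is what the exhaustive
small-universe oracle in the test suite checks, since a two-sided Fisher p
is not an upper-tail sum. Terms with zero DE overlap are retained at p = 1:
they carry no enrichment signal, and reporting a small "depletion" p for an
enrichment screen would be misleading. Each term also gets the GOplot-style
direction summary `z = (up − down)/√(up + down)` over its DE members
(`goplot_zscore()` for a single term), undefined on empty overlaps.

**GSEA.** `gsea()` implements the weighted running-sum statistic: walking
down the ranking, the sum rises by `|score|^weight / Σ|score|^weight` at set
members and falls by `1/(N − K)` elsewhere; ES is the extremum of largest
absolute value. Two numerical choices are explicit: if every hit score is
zero at `weight > 0`, hits fall back to equal weights rather than 0/0; and
an exact |max| = |min| tie — a real possibility at weight 0, where the
running sum lives on a lattice — resolves to the positive extremum, with a
1e-12 tolerance so the choice does not flip on floating-point noise. The
null is gene-label permutation (random same-size sets), chosen over
phenotype permutation because the study's group sizes (3–4) cannot support
the latter; 1000 permutations by default, with fewer than 100 flagged in the
result metadata. NES divides ES by the mean |permuted ES| of matching sign;
the nominal p is the same-sign permutation tail fraction (zero is possible
and means "beyond all permutations"). `run_gsea()` adds the canonical pooled
FDR: permuted ES are NES-normalized per term, pooled across terms, and each
observed NES's null tail fraction is divided by its observed tail fraction,
clipped to [0, 1]. Ranking (`rank_features()`) offers the t statistic
(default) or the signed log2FC, descending, with lexicographic tie-breaks
for determinism; the study does not state its ranking metric, so published
NES values are not reproduction targets.

## Interaction neighborhoods

`read_string_links()` parses the STRING v11.5 `protein.links` dialect
(space-delimited, one header, integer scores 0–999) and divides scores by
1000, so the study's "0.750 or above (out of 1.000 maximum)" is raw ≥ 750.
The two directed rows STRING emits per association collapse into one
undirected edge; if they ever disagree, the maximum is kept with a warning.

`build_seed_network()` takes the induced subgraph on seeds plus anchors over
edges at or above the threshold, then removes isolated nodes — anchors
included, since the study filters "nodes with no interactions with other
nodes" without exception. Seeds absent from the edge list's namespace also
fall to the isolation rule and are additionally reported as `unmatched`.
"k degrees of interaction" is read as shortest-path hop distance *within the
constructed subnetwork* (not within full STRING), computed after isolation
pruning, because the constructed network is the object whose counts the
study reports; edge scores never weight distances. `khop_sets()` returns
exact-distance sets (so "2-degree" excludes "1-degree" members — the study
enumerates the two counts separately, implying disjoint sets), and
`partition_interactors()` classifies non-anchor nodes into unique-to-A,
unique-to-B and mutual within k hops, with the exact-distance sets also
reported so the inclusive reading can be tabulated if wanted. Printed
node/edge counts from the original networks are not asserted anywhere: they
require the study's deposited DE lists and the pinned STRING download, and
the paper itself prints two different edge counts (1562 and 1916) for the
same 126-node network.

## Concordance

`concordance()` joins two differential tables on uppercased feature symbols
(the study compares mouse and human datasets), restricts to a declared
comparison set — significant in both (the study's cross-dataset scatter),
significant in the first, or all shared features — and reports the OLS fit
of B on A with the Pearson r on the same set. Both policies the study uses
coexist and the report records which was applied. Fewer than three
comparable features is an error: the fit is undefined, not zero.

## Bulk RNA-seq

`tpm()` follows the RPK construction exactly: RPK = count/(length in kb),
per-sample factor = ΣRPK/1e6, TPM = RPK/factor, so every column sums to one
million by construction (asserted to 1e-3 absolute). Genes with zero length
are excluded and reported; an all-zero sample is an error. `call_degs()`
tests log2(TPM + 1) with the Student t — the study pairs TPM with t-tests
and names no count model — and applies the preset gates verbatim.

## Single-cell RNA-seq

`qc_filter()` applies the four filters in the study's printed order, each on
the matrix as left by the previous step: cells under 200 detected genes,
genes in fewer than 3 cells, cells over 6100 genes, cells over 7%
mitochondrial UMIs. Order matters — the test suite carries a three-cell
counter-example where gene-first filtering removes a different total — so
the per-step removals are reported and the order is part of the contract.
The mitochondrial fraction is computed on the input matrix before any
filtering (the study does not say; computing it after gene filtering would
make a cell's fraction depend on which genes other cells express), with
"> 7%" strict. Mitochondrial genes default to the mouse `mt-` symbol prefix.

Downstream processing mirrors the standard single-cell stack:
counts-per-10k log1p normalization; HVG selection by variance/mean
dispersion standardized within mean-occupancy bins (bins with fewer than two
genes or zero spread keep the raw dispersion; zero-dispersion genes are
never selected; ties break by gene name); per-gene OLS regression on total
counts and mitochondrial fraction with constant covariates dropped under a
warning (residuals are exactly orthogonal to the covariates); unit-variance
scaling with symmetric clipping at ±10 SD (the upper-only variant behind a
flag; zero-variance genes stay at zero, flagged); and PCA via SVD with
explained-variance ratios for the scree. `per10k_mask()` implements the
study's display rule — a cell counts for a gene iff it has at least one
transcript per 10,000 total counts. `classify_subsets()` gates cells on
CD62L (Sell) and IL-7Rα (Il7r): lo/lo → long-lived effector, lo/hi →
effector memory, hi/hi → central memory, hi/lo → unassigned (no subset is
defined for that quadrant). The original authors' exact cutoffs are not
published ("similar biomarker criteria"); the default — "hi" means at least
1 per 10k counts, i.e. normalized expression ≥ 1 on the CP10K scale — reuses
the study's own per-10k display rule and is overridable.

## The synthetic-data generators

Every generator is a pure function of its parameters and seed and ships a
ground-truth object, so each stage's tests assert recovery against known
truth rather than against another implementation.

* `gen_intensity_matrix()` builds intensities from a copy-number model —
  copies (log-uniform, 1e2–1e7 per cell) × molecular weight × per-sample
  loading scale × log-normal noise — so the proteomic ruler is exactly
  invertible: histone copies are drawn so their summed protein mass equals
  the configured DNA mass (the identity the ruler rests on), and histones
  carry no noise. Knockout shifts of `effect_log2` (random sign) are planted
  in a `de_fraction` of features, restricted to features above the lower
  abundance quintile: the bottom of the range is mostly censored by the
  missingness model, and planting there would measure detectability, not
  test power. Missingness is logistic in standardized log intensity
  (left-censoring), never applied to histones. Defaults (2000 features,
  n = 4/group, 10% DE, 0.25 log2 noise, 10% missing) are desk-scale stand-ins
  for a DIA T-cell proteome.
* `gen_scored_graph()` *constructs* a graph realizing an exact two-anchor
  neighborhood spec (counts at distance 1 and 2 per anchor, mutual overlap)
  instead of rejection-sampling: distance-1 layers hang off each anchor,
  mutual nodes attach to one gateway neighbor per anchor (distance exactly 2
  from both), unique distance-2 nodes spread round-robin over the
  distance-1 layer, and no other inter-layer edges exist, so no shortcut can
  change a distance. Infeasible specs (mutual exceeding a distance-2 count,
  or distance-2 nodes without a distance-1 layer) fail up front with the
  violated constraint. Planted edges draw scores in [threshold, 0.999],
  decoys strictly below, so thresholding at 0.750 recovers exactly the
  planted graph. The default spec plants the study's printed counts
  (11/42, 10/28, 17 mutual).
* `gen_gene_sets()` plants terms with a declared DE overlap among uniform
  decoys; `gen_bulk_counts()` draws negative-binomial counts with a
  gene-length covariate, dispersion 0.01 (biological CV ~10%, the standard
  figure for inbred-mouse replicates) and n = 4/group, planting fold changes
  only in genes with expected count ≥ 20 (the usual filter-by-expression
  floor — an 8-fold change at three reads is a shot-noise question, not a
  test question). Even so, recovery of planted 8-fold effects at p < 0.001
  is ~95–98% per gene, not 100%: occasional NB outlier replicates defeat a
  6-df t-test, which is a property of the design, not a defect.
* `gen_umi_matrix()` builds the sparse UMI matrix deterministically in
  structure (which cell detects which genes; counts are random): passing
  cells draw a fixed number of filler genes round-robin (so every retained
  gene comfortably clears the cells-per-gene filter), and each violator cell
  or gene breaks exactly one QC rule — too few genes, too few cells, too
  many genes, or ~2× the mitochondrial threshold — with classes constructed
  non-overlapping so the per-step removal counts are unambiguous under the
  sequential order. Marker classes (Sell/Il7r hi–lo combinations) are
  planted among passing cells; "hi" is a nonzero marker count, which lands
  well above 1 per 10k at these library sizes.

**What passing tests show, and what they do not.** The generators emulate the
*structure* of the real inputs — log-normal abundance with left-censored
missingness, scored symmetric interaction files, NB counts, sparse UMI
matrices with QC failure modes — under clean, independent noise. They do not
emulate correlated protein complexes, batch effects, ambient RNA or doublets,
isoform-level length ambiguity, or the long-tailed score structure of real
STRING neighborhoods. Green tests therefore certify the *procedures*
(formulas, thresholds, orderings, accounting) and their statistical
calibration under the stated models, not the biological conclusions of any
particular dataset.

## Problem sizes and numerical checks

The test suite and `scripts/acceptance.R` run at sizes chosen to make the
statistical assertions sharp while staying desk-scale: type-I calibration
uses 2000 features × 100–200 replicate matrices (binomial error on 2–400k
tests ≈ 3×10⁻⁴); distance oracles use 200 random graphs of ≤ 25 nodes
against a hand-rolled Floyd–Warshall; GSEA ES is checked exhaustively on all
2–3 member sets over lists of length ≤ 8 against an O(N²) from-scratch
running sum and against an independent implementation (`fgsea::calcGseaStat`)
on larger random cases; ORA is checked against direct hypergeometric
summation over a grid of universes up to N = 50; concordance recovers a
generating ρ within ±0.03 at n = 5000; the ruler inverts noise-free planted
copies to < 1e-6 relative error (observed: machine epsilon). Determinism is
part of the contract: same seed, identical outputs, and the permutation seed
is recorded in every GSEA result.

## Known limitations

* No moderated variance (limma-style) statistics — the study uses plain
  Student tests, and so does the package.
* No peptide-to-protein rollup, imputation, or batch correction.
* STRING's own "PPI enrichment p-value", force-directed layouts, and any
  layout-dependent statistic (the study's "spatially clustered" count) are
  out of scope.
* Clustering (Leiden/Louvain), UMAP and pseudotime are not implemented; the
  single-cell stage stops where the study's subset classification starts.
* Printed node/edge counts of the study's own networks are not asserted:
  they depend on deposited data and a pinned STRING release.
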