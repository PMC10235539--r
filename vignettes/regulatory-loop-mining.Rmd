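---
title: "Mining cell-specific regulatory loops from single-cell transcriptomes"
author: "scRegLoops"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining cell-specific regulatory loops from single-cell transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scRegLoops)
```

# Overview

scRegLoops implements an in-depth mining workflow for annotated single-cell
transcriptomes of case/control tissue — the motivating system is an
RPE/choroid dissociation with roughly eight major cell types sampled from
two ocular regions under a degenerative disease and control condition. The
workflow starts from a log-normalized gene × cell matrix and a per-cell
annotation (type, condition, region, donor) and produces, in order:

1. **Novel marker candidates** ranked by the *cell expression specificity of
   a gene* (CESG),
2. **Cell-type abundance** (ACT) ratios across conditions,
3. **Per-type differential expression** by a Wilcoxon rank-sum test,
4. **Non-negative expression patterns** with per-type predictive power,
5. **Regulon activity and specificity scores** (RAS, RSS),
6. **Cell-specific TF regulatory loops**: ternary cliques of one pattern,
   one regulon and one DEG set whose pairwise gene overlaps are all
   hypergeometrically enriched.

Clustering, cell-type annotation, gene-regulatory-network inference and
ligand–receptor communication inference are deliberately *not* part of the
package: cluster labels, regulon target sets and pathway memberships are
inputs, supplied as a TSV and GMT files. This keeps every score
reproducible from plain-text inputs and makes the package testable without
any external download.

# The scores

## CESG — marker specificity

For gene $i$ and cell type $j$, with $m$ expressing cells among the $M$
cells of the type and $K$ expressing cells among the $N - M$ remaining
cells,

$$\mathrm{CESG}_i = \frac{\mathrm{pct.1}_i}{\mathrm{pct.2}_i}
 = \frac{m/M}{K/(N-M)}.$$

A cell *expresses* a gene when its log-normalized value exceeds a
detection threshold, 0 by default; no canonical cutoff exists, so the
threshold is a parameter. A gene expressed inside the type and nowhere
else has CESG $= \infty$ — the strongest possible marker signal — and a
gene silent in the type has CESG $= 0$.

Novel marker calling composes three gates: the candidate must be
differentially expressed type-vs-rest with `avg_log2FC > 1` and adjusted
$p < 0.05$; it must not be a known marker of the type; and its CESG must
strictly exceed the *reference* CESG of the type's known markers. The
reference is the **maximum** CESG among known markers — the conservative
reading when the comparison against "the known markers" is not pinned down
to a particular summary. When a known marker is itself exclusively
expressed the reference is infinite and only exclusive candidates qualify;
among infinite CESG values ranking falls back to the expressing fraction
pct.1. Literature curation of candidates is out of scope: candidates are
emitted with flags for manual review.

## ACT — abundance of a cell type

The citation trail for ACT stops at a formula the source never prints, so
the package adopts the standard observed/expected (Ro/e-style) ratio:

$$\mathrm{ACT}(c,k) = \frac{n_{ck}/n_k}{n_c/n_\text{total}},$$

the proportion of type $c$ within condition level $k$ over its overall
proportion. This is an interpretive choice, made because it satisfies the
stated "enriched when ACT > 1" semantics and because ratios of published
ACT values reproduce the published fold differences (2.7, 8.5, 1.56)
under it. The weighted mean of ACT over levels is identically 1, so the
ratio is comparable across unevenly sampled conditions. Cells are pooled
across donors; per-donor stratification is available through the `donor`
field. No significance test is attached to ACT, and no shrinkage is
applied to small counts — the counts table is exposed instead so users can
judge stability directly.

## Differential expression

`wilcoxonDE()` implements the two-sided Wilcoxon rank-sum test per gene:
tie-corrected normal approximation with continuity correction, switching
to exact enumeration of all $\binom{n}{n_a}$ rank assignments when the
pooled group size is at most 12 cells. The fold change is the
conventional pseudocounted ratio of de-logged group means,
$\log_2\frac{\text{mean}(\mathrm{expm1}(x_a)) + 1}
{\text{mean}(\mathrm{expm1}(x_b)) + 1}$. Multiple testing uses
**Bonferroni** over the tested genes (the default of the tooling the
thresholds were inherited from), and DEGs are called at
$|\text{avg\_log2FC}| \ge 0.25$ (inclusive) and adjusted $p < 0.05$
(strict). All genes expressed in at least one cell of either group are
tested; there is no minimum-fraction prefilter by default.

## Patterns and predictive power

`nmfDecompose()` factorizes the non-negative expression matrix into
amplitude (gene weight) and pattern (cell weight) matrices by seeded
Lee–Seung multiplicative updates on the Frobenius objective. A standard
seeded NMF stands in for Bayesian sparse CoGAPS: downstream the
decomposition is used only as a source of cell-associated gene sets, which
NMF provides reproducibly at desk scale (same seed, bitwise-identical
factors). The objective is non-increasing at every update; iteration stops
on a relative error change below `tol`. Convergence depth matters more
than it may appear: factors stopped early still reconstruct well but carry
residual cross-type loading in their cell weights, which inflates the
predictive power of a pattern for *unrelated* cell types. The pipeline
default (`max_iter = 300`, `tol = 1e-7`) is chosen so factors on the
default synthetic data are clean in this sense.

Predictive power of a pattern for a type is the AUROC (midrank convention)
of its cell weights for discriminating that type's cells from all others,
optionally stratified by condition. Patterns with power $\ge 0.7$
(inclusive) are *selected* for a type. Pattern gene membership — needed for
the overlap tests but never defined upstream — defaults to the **top 50
genes by amplitude weight**, a declared choice configurable as a count or
a weight quantile.

## Regulon activity and specificity

Regulons (TF → target sets) are inputs. `computeRAS()` scores each regulon
in each cell AUCell-style: genes are ranked by decreasing expression, ties
broken by a fixed permutation seeded from the cell's column index (making
the score deterministic for a given matrix), and the score is the area
under the target-recovery curve within the top 5% of ranks, normalized to
its maximum. `computeRSS()` converts activity to per-type specificity,

$$\mathrm{RSS}(R,C) = 1 - \mathrm{JSD}(P^R, P^C),$$

where $P^R$ is the activity vector normalized to sum 1 and $P^C$ the
uniform indicator distribution over the type's cells. The
Jensen–Shannon divergence uses log base 2 so RSS lies in $[0,1]$; the
$1-\mathrm{JSD}$ form is used as printed even though some upstream
implementations use $1-\sqrt{\mathrm{JSD}}$. Selection gates: a regulon is
**cell-type-specific** for type $c$ when $\mathrm{RSS}(r,c) \ge 0.1$ and
the Z-score of its mean RAS in $c$, standardized across cell types, is at
least 2 ("Z ≥ 2, evaluated across all cell types" is the reading adopted
for an ambiguously worded rule; note that with fewer than six cell types a
one-hot activity profile cannot reach Z = 2 at all, and with fewer than
three the Z-score is undefined — the function then refuses). A regulon is
**disease-associated** for a type when the magnitude of its
condition-wise RSS log2 fold change exceeds 1; fold changes are computed
by re-scoring RAS/RSS within each condition and are clipped to $\pm 10$,
the sentinel used when one condition's RSS is 0.

## Loop construction

Within each cell type, selected patterns, selected regulons and the
type's DEG set are tested pairwise (cross-kind only) for overlap
enrichment. The printed overlap formula is the hypergeometric point mass
$\binom{M}{k}\binom{N-M}{n-k}/\binom{N}{n}$; a point mass cannot serve as
a "$P < 0.05$" gate coherently for large sets, so the edge statistic is
the standard over-representation upper tail $P(X \ge k)$, with the point
mass exposed separately (`hypergeomPmf()`) for exact comparison. The
universe $N$ is all genes of the analyzed matrix (configurable to the
union of tested sets). No multiple-testing correction is applied to
$P_\text{loop}$ by default, matching the raw 0.05 gate; a BH option
exists. A **ternary loop** requires all three pairwise edges significant —
the strictest reading, since requiring only two of three is never stated.
Cell-type loops use type-vs-rest DEG sets with cell-specific regulons;
disease loops use within-type condition DEG sets with disease-associated
regulons and condition-stratified pattern power. Pathway annotation is
pure set membership against user-supplied GMT pathways (at least one
shared gene by default); no communication inference is performed.

# The synthetic generator

`simulateDataset()` draws counts per gene × cell from a negative binomial
with gene-specific log-normal baseline means (meanlog $\log 0.5$, sdlog 1,
size 2) and then library-size normalizes (common library $10^4$) and
log1p-transforms — the pipeline consumes normalized expression, so raw
count QC and variance-stabilizing machinery stay out of scope. The default
configuration is 8 cell types × 2 conditions × 100 cells and 2,000 genes,
a deliberate ~5× reduction of a typical RPE/choroid dissociation in both
directions that preserves per-type cell counts of realistic magnitude.

Planted structure, all multiplicative on the mean scale:

* **Markers** (2 per type; 1 emitted as "known", the rest to be
  rediscovered): mean zero outside the type, within-type mean ×
  $e^{3}$. Exclusivity is what "marker" means here; a generator gene
  expressed broadly would not be a marker at any effect size. Setting
  `marker_effect = 0` disables marker planting entirely so null data are
  truly null.
* **Condition DEGs** (20 per type, half up, half down, shift $e^{1.5}$):
  planted on expressed genes — baselines floored at the baseline law's
  median — because a shift on a gene the assay rarely detects is
  unidentifiable by any method.
* **Programs** (one per type, 50 genes, elevation $e^{1.5 w_g}$ with
  per-gene weights $w_g \in [0.5, 1]$).
* **Regulons** (one per type, 30 targets, elevation $e^{2}$ in the type;
  plus one disease-only regulon active in a single (type, disease)
  stratum).
* **Ternary loops**: 10 genes shared per type among its program, its
  regulon's targets and its DEG set.

Region labels carry no signal by default; regional abundance analysis is
exercised by configurations with explicit per-type region odds (e.g. 8:1).
Donors are two per condition with no donor effect. Everything is a
deterministic function of the seed.

What the generator does *not* emulate: doublets, ambient RNA, batch and
donor effects, gene–gene correlation beyond the planted blocks, and the
empirical depth distribution of any particular platform. Passing
recovery tests on these data therefore demonstrates the correctness and
calibration of the scoring chain, not robustness to real-data artifacts.

One emergent behavior worth knowing: planting activity into a subset of
cells changes their library size, so after normalization *unplanted* genes
shift slightly in the opposite direction within those cells. This
compositional coupling is a property of library-size normalization itself;
with enough cells it can push high-expression bystander genes past the DEG
gates. The false-positive guarantees of the DE stage are therefore stated
and tested on null data, where they hold comfortably under Bonferroni.

# Numerical and design notes

* All internal indexing is by gene/cell identifier; 1-based MatrixMarket
  coordinates exist only on disk. Gene symbols are matched exactly and
  case-sensitively — no alias resolution, since silent symbol mapping is a
  reproducibility hazard.
* Input expression is assumed log-normalized; `raw_counts = TRUE` on the
  readers applies library-size + log1p normalization once at load.
* The exact Wilcoxon branch enumerates rank assignments, so it is valid
  under ties; the normal branch applies the tie correction
  $\sum_t (t^3 - t)$ and a 0.5 continuity correction, which keeps it
  within $|\Delta p| \le 0.02$ of the exact branch at 6 vs 6 and holds the
  empirical size at 5% on null negative-binomial data.
* Degenerate inputs fail loudly: all-zero matrices and out-of-range ranks
  for NMF, single-type partitions for CESG's pct.2, fewer than three cell
  types for the regulon Z-score, empty condition levels for ACT, and
  hypergeometric parameter violations each raise a named error. Empty gene
  sets never enter an overlap test.
* RAS tie-breaking uses a per-cell seeded permutation rather than midranks
  so that the recovery curve is defined over a strict ordering, as the
  rank-window construction requires; the per-cell seed keeps it
  deterministic.
* Problem sizes used by the shipped tests: the unit suite runs on a
  6-type × 40-cell × 1,000-gene reduction whose planted blocks keep the
  same proportions relative to the 5% AUCell window; recovery claims at
  the default scale (8 × 100 × 2,000, ten seeds) are exercised by the
  acceptance suite, with a stronger condition shift ($e^{2.5}$) in the
  reduced fixture compensating its halved group sizes.

# Limitations

* Regulon inputs are trusted as given; no motif or coexpression evidence
  is re-evaluated.
* The hypergeometric overlap test treats genes as exchangeable; correlated
  gene modules inflate overlap under the null, so loop p-values on real
  data are optimistic and the alpha gate should be read as a screen, not
  an error rate.
* Pattern gene membership (top-50) and the detection threshold for
  "expressing" are conventions, not estimates; conclusions sensitive to
  them should be checked across settings.
* Published marker genes, DEG counts and TF fold changes from the
  motivating tissue datasets depend on those datasets and are not
  reproduction targets of this package.
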