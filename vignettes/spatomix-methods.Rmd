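---
title: "Methods: admixture-aware spatial and single-cell TME analysis"
author: "spatomix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: admixture-aware spatial and single-cell TME analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`spatomix` implements the bespoke computational stages of a joint
scRNA-seq + Slide-seqV2 analysis of tumor microenvironments: gene-set
signature scoring, derivation of a compact tumor signature with ROC
evaluation on bulk cohorts, Moran's I cell-type spatial autocorrelation,
tumor / tumor-adjacent context segmentation, admixture-corrected
context-dependent differential expression (DE), and ligand-receptor (LR)
screening by permutation tests, both on dissociated data and on spatial
k-nearest-neighbor (kNN) graphs. A synthetic-data module generates
scRNA-like, Slide-seq-like and bulk datasets with known ground truth, so
every stage is testable without external downloads.

Upstream steps that established tools already solve — alignment, barcode
processing, doublet scoring, graph integration and embedding, spot
decomposition, CNV inference — are out of scope; their outputs (counts,
doublet scores, bead cell-type calls with singlet/doublet-certain/reject
confidence classes) are inputs here.

# Data model and quality control

`ExpressionDataset` and `SpatialDataset` extend `SingleCellExperiment`:
sparse integer `counts` with per-cell metadata (`sample_id`, `fraction`
&#8712; {healthy, adj_normal, tumor}, `cell_type`, optional `subtype`,
`malignant`, `doublet_score`) or per-bead micron coordinates plus
`cell_type` and `annotation_class`. Validity methods enforce integer
non-negative counts, unique gene ids, the fraction and annotation-class
vocabularies, and finite coordinates.

Quality-control boundaries follow the conventions of droplet and bead
platforms and are deliberately strict at the cut points:

* `filterCellsByUMI(x, 600)` keeps cells with **at least** 600 total UMI
  (cells with *less than* the threshold are removed); the same rule at 100
  UMI serves Slide-seq beads.
* `filterDoublets(x, 0.4)` removes cells whose doublet score is **strictly
  above** 0.4.
* Only singlet and doublet-certain beads enter pseudo-bulk profiles, LR
  screens and autocorrelation; reject beads are excluded.

# Normalization

`normalizeDepth` rescales each cell to a fixed total (default
`scale_constant = 1e4`), linear scale. No log transform is applied by
default because both the signature score (a mean of normalized magnitudes)
and the LR scores (products of normalized magnitudes) are defined on linear
expression; `log1p = TRUE` is available but off. Zero-depth columns stay
zero with a warning. The scale constant is exposed because the original
workflows do not pin down the normalization totals; all thresholds quoted
here (e.g. the 0.1 malignant-call score) are interpreted on the normalized
scale in use.

# Signature scores and group comparisons

The score of a cell for a gene set is the arithmetic mean of the set's
genes' normalized expression; absent genes are dropped with a warning (an
error if no gene overlaps). Sample-level scores are exact means over the
sample's cells, optionally stratified (fraction, cell type).

Group differences are assessed with the two-sided Wilcoxon rank-sum test.
When both groups have at most 8 observations the p-value is computed by
full enumeration of all label assignments on midranks — exact even under
ties, where the classical exact algorithm is unavailable; larger groups use
the normal approximation with tie-corrected variance and continuity
correction. The signed Z statistic used throughout is the standard-normal
quantile of the two-sided p, signed by the direction of the mean
difference. This Z-from-p construction is the package's explicit,
re-checkable definition for marker strength.

The inter-individual expression distance (per fraction) between two
samples is `1 - Pearson r` of their per-cell-type mean normalized profiles,
averaged over cell types with weights `min(n_cells_a, n_cells_b)` per type
and a 10-cell minimum per (sample, type) profile. The min-count weighting
is a design choice: the least-sampled side of a pair bounds how much that
cell type's profile can be trusted. It is symmetric, zero for identical
samples and bounded by 2.

# Tumor signature

`rankMarkers` tests each gene malignant-vs-normal on normalized expression
(rank-sum as above) and reports the detection fraction (share of cells with
raw count > 0 — "expressed" means detected at least once).
`deriveSignature` keeps genes with **Z strictly above 3**, upregulated in
the malignant group, whose detection fraction across all healthy epithelial
cells is **strictly below 5%**; genes are ordered by descending Z. Cells
are called malignant when their signature score is **strictly above 0.1**.
All three cut-offs are strict inequalities, matching the "greater than" /
"less than" wording of the rules they encode. `evaluateBulkAUC` scores bulk
samples by the unstandardized mean of signature genes (a per-gene z-score
option exists) and computes AUC as the Mann-Whitney concordance
probability, ties counted one half — identical to U/(n1·n2) of the rank-sum
statistic, which the tests cross-check.

# Spatial statistics

`buildKnnGraph` builds Euclidean kNN (default k = 10) with deterministic
tie-breaking toward the lower bead index, symmetrizes edges by union and
uses binary weights. `moransI` is textbook Moran's I,

$$I = \frac{n}{\sum_{ij} W_{ij}}\;
\frac{\sum_{ij} W_{ij}(x_i-\bar x)(x_j-\bar x)}{\sum_i (x_i-\bar x)^2},$$

with optional row standardization (default on; the leading factor is then
1). Cell-type autocorrelation applies it to the binary membership indicator
over non-reject beads; indicator values rather than decomposition weights
are used because bead calls are categorical after decomposition. Absolute
values depend on the weighting scheme, so analyses should compare orderings
across cell types or conditions rather than absolute magnitudes.

`segmentContexts` automates the tumor / tumor-adjacent partition that was
originally drawn by hand: per bead, the local tumor fraction among
non-reject beads within `smoothing_hops` graph hops (inclusive of self) is
thresholded at `density_threshold` (default 0.3, inclusive). Both knobs are
exposed; 0.3 with one hop recovers half-plane domains to within one hop of
the boundary in the bundled simulations.

# Admixture correction and context DE

Slide-seq beads carry transcripts from neighboring cells of other types;
in a tumor-dense context the contamination is tumor-biased, so naive
context DE of a target cell type rediscovers its neighbors' markers. The
correction is a constrained linear regression: with the observed target
pseudo-bulk normalized to proportions $y$ and normalized reference profiles
$P$ (target's own profile included as a column),

$$\hat w = \arg\min_{w \ge 0} \lVert y - P w \rVert_2,$$

solved by Lawson-Hanson NNLS and reported normalized to sum 1, with the
design's condition number and the residual norm. Designs with condition
number above 1e8 trigger a warning and a ridge-regularized fallback,
flagged in the fit. Weight estimation happens in proportion space (depth
cancels), the subtraction in count space:
`corrected = observed - depth * sum_k w_k P_k` over contaminant types only,
floored at zero and rounded so the result remains count-like. The target's
own component is retained, i.e. correction removes foreign signal without
rescaling the target. This proportion-space-fit / count-space-subtraction
split, with no intercept and a non-negativity constraint, is the package's
central interpretive decision for the correction; it makes noiseless
mixtures exactly recoverable and keeps the DE input integer.

Context DE then compares corrected pseudo-bulk replicate profiles between
tumor and adjacent contexts with a self-contained negative-binomial test:
library-size offsets, per-gene method-of-moments dispersion pooled within
groups and shrunk toward the common (median) dispersion with 10 prior
degrees of freedom, a per-gene NB GLM at fixed dispersion, and a Wald
statistic on the log2 fold change referred to a t distribution with
residual + prior degrees of freedom — the moderated-statistic convention:
the shrunken dispersion is worth roughly its prior df of extra information.
This engine is deliberately self-contained and validated by calibration and
power properties (type-I error 0.05 at nominal 0.05 under label
permutations; planted effects recovered) rather than by matching another
package's numbers; an independent DE engine is used in the test suite only
as a fold-change cross-check. BH is the multiple-testing adjustment
throughout the package.

Replicates: with replicate pucks per condition, pucks are the replicates.
With a single puck, disjoint spatial tiles (`tilePuck`, or custom strata)
stand in — a documented fallback; tiles of one puck share technical factors
that true replicates would not, so single-puck inference is weaker.
`fractionDE` applies the same engine to per-sample pseudo-bulk of one cell
type between sample fractions, excluding samples with fewer than 10 cells
of the type.

Total-count normalization of pseudo-bulks makes the test sensitive to
composition shifts when a large share of the transcriptome changes in one
condition; with signatures of tens of genes on a realistic transcriptome
this is negligible, but pathological simulated inputs (half the counts
planted) would require a robust normalization not implemented here.

# Ligand-receptor screening

Dissociated mode: a pair's score for sender type A and receiver type B is
the product of mean normalized ligand expression in A and mean normalized
receptor expression in B, restricted to genes detected in at least 10% of
the type's cells (inclusive). The null shuffles cell-type labels over all
cells (1,000 rounds by default).

Spatial mode: on the kNN graph with symmetric binary adjacency $M$,

$$S = \sum_{i \in A}\sum_{j \in B} L_i R_j M_{ij}
    - \sum_{i \in A}\sum_{j \in B} R_i L_j M_{ij},$$

directional ligand-receptor co-expression across adjacent beads minus the
gene-swapped term, which absorbs symmetric admixture leakage (ligand
bleeding into receivers and vice versa). The score is computed by sparse
products and verified against the brute-force double loop in the tests.
The null shuffles bead labels globally across the puck (2,000 rounds by
default) while expression stays attached to positions. p-values are
one-sided upper-tail with the +1 pseudo-count — positive S is the
directional co-expression the screen looks for; `runLRScreen` shares the
permutation draws across pairs within a round for efficiency, reports
untested (filter-failing) pairs explicitly, and BH-adjusts across all
tested rows. The 10% detection filter is applied in spatial mode on
bead-level detection per annotated type — an extension of the dissociated
rule, documented here because bead detection is sparser than cell
detection.

# Synthetic data: what it emulates and what it does not

All generators draw negative-binomial counts parameterized by mean $m$ and
dispersion $\varphi$ (variance $m + \varphi m^2$; $\varphi = 0$ is
Poisson), are bit-reproducible under a fixed seed, and return their ground
truth (planted effects, per-bead mixing weights, planted LR pairs).

* `simulateProfiles`: log-normal per-gene baselines shared across types;
  each type gets disjoint marker genes at `marker_fold` (default 4) above
  baseline.
* `simulateScrna`: defaults mirror a multi-donor prostate design — 5
  healthy, 14 adjacent-normal, 17 tumor samples; log-normal library sizes
  (median 2,000 UMI); optional per-sample, per-gene log-normal random
  effects emulate inter-individual variability; planted fold changes per
  (gene, type, fraction).
* `simulatePuck`: jittered hexagonal bead layout at 20 µm spacing
  (mimicking ~10 µm beads; a Poisson layout is available), rectangular
  domains with per-domain compositions. A bead's expected expression is
  `self_weight` × its own type's profile plus the rest distributed over
  neighboring beads' types with Gaussian distance weights (bandwidth 30 µm,
  truncated at 3 bandwidths). `self_weight` defaults to 0.7: Slide-seq
  beads are near-single-cell but measurably contaminated, and no published
  quantification pins the rate, so it is an explicit knob, not a platform
  claim. Context effects modify the target type's profile inside designated
  domains only; planted LR pairs multiply ligand expression in sender beads
  that have a receiver-type bead within one bandwidth (and receptor in
  those receivers) — exactly the adjacency-conditional coupling the spatial
  score detects.
* `simulateBulkCohort`: samples are composition-weighted sums of type
  profiles under log-normal noise — the structure of bulk validation
  cohorts.

Not emulated: transcriptome-wide gene-gene correlation, cell-cycle
structure, segmentation artifacts, spatial platform noise beyond NB +
admixture, and real marker-gene identities. Passing tests therefore
demonstrate the statistical machinery under the stated generative
assumptions, not performance on any particular tissue.

# Numerical choices and degenerate inputs

* Strict vs inclusive boundaries are as documented per filter (UMI and
  detection filters inclusive-keep; doublet, Z, healthy-fraction and score
  thresholds strict).
* kNN ties break toward the lower index; graph construction is
  order-invariant up to that rule.
* Moran's I on constant values errors ("zero variance"); all-zero genes get
  Z = 0 and p = 1; empty signatures are returned with a warning, not an
  error.
* NNLS degenerate designs fall back to ridge (flagged); an all-zero fit
  degenerates to target weight 1.
* Corrected profiles are floored at 0 and rounded; with zero contaminant
  weights correction is the identity.
* Permutation p-values use the +1 pseudo-count, so p &#8805;
  1/(n_perm + 1).
* Seeds: every stochastic operation takes an explicit seed (default 0) and
  restores the caller's RNG state.

# Problem sizes used by the test suite

The bundled property checks run at sizes chosen to make their statistical
assertions sharp while staying desk-scale: oracle equivalence of the
spatial score on 200 random instances up to 300 beads; 1,000 antisymmetry
instances; calibration from 2,000 rounds per LR mode (199 permutations
each) and 200 label-permutation rounds of context DE; planted-LR power over
50 pucks of ~290 beads with 5 planted and 95 decoy pairs at 999
permutations; 20 confound-only pucks and 5 planted-effect pucks (2,000
genes) for the correction; 100 deconvolution fits per noise regime, with
pseudo-bulk-scale dispersion 0.01 at 1e5 total counts (bead-level
dispersion ~0.1 aggregated over tens of beads); 100 paired
clustered-vs-dispersed Moran comparisons.

# Known limitations

The admixture correction assumes contamination is a non-negative linear
mixture of *known* reference profiles on a shared gene universe; missing
contaminant types inflate the target weight and leave residual confounding.
Context segmentation assumes tumor density is locally smooth at the chosen
hop radius. The LR screen tests adjacency-scale co-expression only — no
secretion range, no multi-subunit complexes, single-gene ligands and
receptors. The spatial Moran's I values are weighting-dependent and should
be read comparatively. Single-puck tile replicates understate
between-replicate variability.
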