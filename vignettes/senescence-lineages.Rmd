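---
title: "Dissecting replicative senescence states and lineages from single-cell transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting replicative senescence states and lineages from single-cell transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis and its assumptions

Cultured mouse embryonic fibroblasts (MEFs) under atmospheric oxygen senesce
replicatively, but not in lockstep: at a passage where roughly half the
culture stains SA-β-Gal positive, individual cells span the whole range from
actively proliferating to deeply senescent, and a few secrete
senescence-associated secretory phenotype (SASP) factors that can push their
neighbours toward senescence. `senlineage` implements, as reusable and tested
R functions, the chain of computations needed to resolve that heterogeneity
from an expression matrix:

1. **QC and feature selection** — cells with too few detected genes are
   removed; expressed genes are those with `ln(mean RPKM) > 0.01`
   (single-cell rule) or `FPKM > 1` in every passage (bulk rule); highly
   variable genes (HVGs) are ranked by *normalized dispersion*: the
   variance/mean ratio of log expression, z-scored within 20 equal-frequency
   mean-expression bins.
2. **Clustering** — PCA on the centered, unit-scaled HVG submatrix (top 50
   components); a symmetric union KNN graph (k = 10, Euclidean in PC space);
   Louvain modularity optimization over a resolution sweep (0.8–2.0, step
   0.2); cluster-vs-rest differential expression (Wilcoxon rank-sum on log
   values, BH-corrected, DEG at q < 0.05 and |log2FC| > 0.25); clusters
   that cannot be distinguished from their nearest neighbour are merged.
3. **Per-cell gene-set activity** — the recovery-curve AUC: genes are ranked
   per cell by decreasing expression, the recovery curve counts set members
   encountered walking down the ranking, and the area over the top T = 3,000
   ranks, normalized by the maximum attainable area, is the activity score;
   scores are Z-normalized across cells per set.
4. **Trajectories** — cluster centroids (first 10 PCs) joined by a minimum
   spanning tree rooted in the proliferating cluster; lineages are
   root-to-leaf paths; per lineage, a principal curve assigns each member
   cell an arc-length pseudotime; projection weights below 0.6 are dropped.
5. **Regulons** — per transcription factor, candidate targets are genes with
   Pearson r ≥ 0.3 to the TF; candidates are pruned by whole-genome motif
   rankings (recovery AUC of the module in the top 5% of each ranking; a
   motif supports the regulon at NES ≥ 3); regulon activity per cell is the
   same recovery AUC, and a regulon is *lineage-committed* when its
   normalized activity correlates with pseudotime at |r| > 0.3.
6. **Bulk integration** — cluster pseudo-bulk averages; consecutively
   monotone genes along a PD6–PD11 passage series; the three-way
   expressed-gene overlap; and a joint PCA of bulk samples with cluster
   pseudo-bulks, whose first component is expected to absorb the platform
   difference so later components carry shared biology.

The pipeline assumes a *continuum sampled at one time point*: states are
discrete enough for graph clustering, yet ordered along smooth expression
gradients that principal curves can recover. It starts from expression
matrices; alignment and quantification are out of scope.

# Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `min_detected_genes` | 2000 | cell QC floor on detected (nonzero) genes |
| `hvg_size` | 2500 | HVG panel (2,500/5,000/8,000 sweep for stability) |
| `n_pcs` | 50 | PCA components carried forward |
| `knn_k` | 10 | neighbours per cell in the KNN graph |
| `resolutions` | 0.8–2.0 | Louvain resolution sweep |
| `deg_q`, `deg_lfc` | 0.05, 0.25 | DEG thresholds (q, |log2FC|) |
| `min_up_degs` | 10 | merge threshold on distinguishing up-DEGs |
| `auc_top` | 3000 | recovery-curve rank cutoff T |
| `weight_cutoff` | 0.6 | pseudotime projection-weight retention |
| `coexpr_r` | 0.3 | TF–target co-expression threshold |
| `top_fraction`, `nes_min` | 0.05, 3 | motif pruning window and NES cutoff |
| `commitment_r` | 0.3 | lineage-commitment |r| threshold |

All of these are fields of `pipeline_config()` and are validated with the
offending field named.

# Design decisions where the design was open

**"log(exp) > 0.01".** The expressed-gene rule is interpreted as the natural
log of the per-gene mean RPKM across cells, treated as a fixed threshold;
the realized quantile it corresponds to is reported as an attribute, since
on any given dataset the two framings need not coincide.

**Merging by distinguishing markers.** "Few DEGs" is operationalized as few
genes upregulated *relative to the nearest cluster by centroid distance*,
not relative to the pooled rest. The two halves of a randomly over-split
cluster inherit every parent marker against the rest, so a vs-rest count can
never trigger the re-merge that motivates the step; the pairwise count
triggers it exactly when the split is uninformative. The reported DEG table
remains cluster-vs-rest.

**Outlier flagging is off by default.** `flag_outliers()` implements robust
per-component z-scores (|x − median| / (1.4826·MAD) > z\_max on any of the
top 10 PCs), but rare genuine subpopulations are indistinguishable from
artifacts under this rule — a 7% subpopulation sits far outside the MAD of
its marker component by construction. The pipeline therefore defaults to
`outlier_z = Inf` and leaves the threshold to the analyst.

**AUC normalizer and tie-breaks.** The recovery AUC is normalized by the
maximum attainable area (all set genes packed at the top), making scores
comparable across set sizes, with rectangle (right-endpoint) integration.
Expression ties — ubiquitous among zeros — are broken by a seeded random
permutation shared across cells, so rankings are reproducible, no gene is
systematically favoured, and identical profiles rank identically.

**Pseudotime weight kernel.** Only the 0.6 cutoff is prescribed by
convention; the weight itself is Gaussian in the projection distance,
`exp(−d²/σ²)` with σ the median projection distance over all (cell,
lineage) pairs, normalized to sum to one per cell. Cells of single-lineage
clusters get weight 1; trunk cells split weight across lineages and
typically fall below the cutoff.

**Resolution selection.** The sweep returns one post-merge partition per
resolution; the pipeline keeps the smallest resolution whose cluster count
equals that of the next grid point (a stability rule), falling back to the
last grid point.

**Monotone = strictly monotone.** A passage-series gene is "consecutively"
up- or downregulated only if every consecutive step moves strictly in the
same direction; a `slack` option tolerates flat steps for sensitivity
analysis.

# The synthetic experiment

`preset_config("mef175")` emulates the structure of the motivating
experiment: 175 cells, 10,000 genes, six states with proportions (0.20,
0.24, 0.23, 0.19, 0.07, 0.07) on the topology 1→2 branching into 2→3→4,
2→5 and 2→6 — a proliferating root, a transition state, two senescent
states, and two small fates ("duplication-regained" and
"translation-elevated"). Per cell, log-mean expression is baseline plus
program loadings times piecewise-linear activations of true pseudotime;
counts are negative-binomial (size 60) with logistic dropout (midpoint 0.5,
steepness 2.5 on the log-mean scale; steepness ≤ 0 disables dropout
entirely), normalized to RPKM-like values by median-of-ratios size factors.
Twelve percent of background genes form a weakly expressed tail so the
expressed-gene filter removes a realistic fraction.

Choices worth calling out:

* **Plateau-and-ramp activations.** Program changes are concentrated in
  ramps of width 0.3 around state boundaries, with plateaus inside states.
  This encodes the modelling assumption that the six states are discrete
  cell identities connected by short transitions; it is also what makes the
  state count recoverable — had the programs drifted continuously within
  states, any graph clustering would legitimately cut the continuum into
  more pieces. The activations remain continuous and strictly monotone at
  the six bulk sampling points, so the monotone-gene ground truth is exact.
* **Effect sizes and noise** (log-fold ≈ 3 for state programs, 2.5 for TF
  programs, NB size 60, deep baseline of ~30 counts) are calibrated so the
  synthetic data reproduces the reported properties of the real experiment —
  six clusters, three lineages, and top-50 PCs explaining > 90% of the
  scaled HVG-matrix variance. They model a deep full-length protocol
  (millions of reads per cell), not shallow droplet data.
* **Scattered SASP.** SASP genes (80, effect 0.8) are elevated only in a
  Bernoulli(0.3) subset of senescent-state cells. The block is deliberately
  weak per cell: a subpopulation signature stronger than the aggregate noise
  floor of the HVG panel would make the SASP-positive cells a seventh
  cluster, contradicting the scattered phenotype; in aggregate the
  recovery-AUC score still separates SASP-positive cells clearly.
* **Composition-robust normalization.** Size factors are median-of-ratios
  rather than total-count: senescent cells carry a heavy program load, and
  total-count scaling would deflate every background gene in exactly those
  cells, inverting planted contrasts (including the SASP pseudo-bulk
  contrast) with a normalization artifact.
* **TF activation shapes are near-orthogonal.** One TF (the planted
  senescence driver) follows the monotone senescence staircase; the others
  follow fate indicators, a transition bump, or proliferation-linked
  declines. If several TFs shared the monotone axis, their modules would
  absorb each other's targets and the motif NES would be diluted below any
  sensible cutoff — a real failure mode of co-expression module inference
  worth emulating only deliberately.
* **Motif database.** Each TF gets one true motif (90% of targets drawn
  uniformly within the top 1% of ranks, 10% scattered genome-wide) and
  three uniform decoys annotated to the same TF. A database must comfortably
  exceed 10 motifs for NES ≥ 3 to be attainable at all: with n motifs, a
  single enriched motif's NES is bounded near (n−1)/√n.
* **Bulk series.** Six passages are main-lineage expectations at increasing
  pseudotimes with a per-gene platform offset (SD 1.5 in log space) and
  lognormal noise (SD 0.1). The platform offset is what makes the first
  joint-PCA component a data-type axis, as in the real comparison.

**What passing tests do and do not show.** The generator plants exactly the
structure the method assumes: negative-binomial noise, state plateaus, one
coherent driver per regulon, no batch effects, doublets, or cell-cycle
confounding beyond the planted proliferation program. Recovery on this data
validates the implementation — that the statistics compute what they claim
and the pipeline recovers planted truth under its own assumptions — not the
biological conclusions of any real experiment.

# Numerical choices and degenerate inputs

* HVG ties are broken lexicographically by gene id; a zero-variance bin
  yields normalized dispersion 0.
* Zero-variance genes are dropped before PCA scaling; variance fractions are
  reported against the scaled panel total, so they are non-increasing and
  sum to one.
* The Wilcoxon rank-sum is the tie- and continuity-corrected normal
  approximation, vectorized over genes (it matches `stats::wilcox.test`
  to ~10 decimal places on untied data); log2 fold changes compare group
  means on the expression scale, so a doubled gene has log2FC exactly 1.
* Principal-curve iteration stops when mean projected-point movement falls
  below 1% of the lineage cloud's RMS radius, or at 15 iterations with a
  warning; duplicate consecutive curve vertices are collapsed.
* The recovery AUC of an empty-intersection set is an error, not NaN; a
  set with identical AUC across cells gets Z ≡ 0; MAD-zero components are
  skipped in outlier flagging with a warning.
* Every stochastic step (generation, tie-breaking, Louvain, tSNE) draws
  from a stage-derived seed and restores the caller's RNG state, so reruns
  are bit-identical and independent of call order.

# Problem sizes used by the test suite

Unit tests run on a 60-cell × 500-gene `tiny` preset and on small closed-form
fixtures; the acceptance properties run the full pipeline on five seeded
replicates of the 175-cell `mef175` preset, each taking on the order of
fifteen seconds. These sizes were chosen to exercise every stage at the
scale of the motivating experiment while keeping a full check of the package
comfortably interactive.

# Known limitations

* Co-expression modules are activating only (positive correlation);
  repressive regulons are out of scope.
* The MST-plus-principal-curve trajectory captures the documented core of
  simultaneous-principal-curve methods but not their joint curve
  refinement; branch points are inherited from clustering, never inferred
  independently.
* The tSNE map is visualization only; no downstream stage consumes it.
* Gene identifiers are matched by exact, case-sensitive string equality;
  there is no symbol-mapping layer.
* On data with genuinely continuous (plateau-free) drift, the state count
  returned by clustering plus merging reflects the resolution rule as much
  as the data; the panel-stability report is the intended guard.
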