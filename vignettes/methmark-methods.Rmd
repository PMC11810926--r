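---
title: "Methods: multi-cancer methylation biomarker panels in methmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-cancer methylation biomarker panels in methmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methmark)
```

## The problem

Aberrant CpG methylation is one of the earliest detectable molecular changes
in carcinogenesis: tumor-suppressor promoters gain methylation, oncogene
loci lose it. On Illumina 450K-style arrays methylation at a probe is
summarized as a beta-value — methylated signal over total signal, bounded in
[0, 1]. `methmark` implements a pipeline for finding a *small panel* of
methylation markers that separates tumor from normal tissue *across several
cancer types at once*, so that a single inexpensive assay (e.g.
methylation-specific PCR on a handful of loci) can serve as a broad
early-screening tool. The pipeline combines three orthogonal sources of
evidence: differential methylation, comorbidity-derived gene-disease
associations, and Gene Ontology functional structure.

## Differential methylation (primary markers)

For each probe, within each group (tumor, normal) separately, outliers are
removed with Tukey fences: values outside `[Q1 - k*IQR, Q3 + k*IQR]` with
`k = 1.5` and type-7 (linearly interpolated) quartiles are discarded. Probes
left with fewer than `min_group_size_after_outliers = 3` samples in either
group are dropped. Filtering per group, not pooled, matters: a genuine
tumor/normal difference pooled into one vector would label one group's
values as outliers and erase the signal.

The effect size is the group-mean difference
`Δβ = mean(β_tumor) - mean(β_normal)`; significance is a two-sided Welch
t-test on the post-filter values, with Benjamini–Hochberg adjustment across
all surviving probes. A probe is a differentially methylated position (DMP)
at `|Δβ| ≥ 0.35` and adjusted p `< 0.01`. A gene is a **primary marker**
when at least one of its probes strictly exceeds the `|Δβ|` threshold with
adjusted p below `gene_q_threshold`, by default restricted to
promoter-region probes (promoter DMPs are the ones that plausibly silence a
gene; the restriction is a switch, `promoter_only`). The gene's reported Δβ
is the signed value of its strongest qualifying probe.

Design choices worth stating:

* **Welch t-test.** The upstream literature is vague about the per-probe
  test. We use Welch rather than a moderated/empirical-Bayes test because
  the decision surface here is the Δβ threshold — the q cut mostly prunes
  flat probes — and Welch needs no cross-probe variance model. Removing
  distribution tails before a t-test makes it mildly anticonservative; the
  type-I property tests therefore run with filtering disabled, and the
  thresholded calling step is validated by planted-truth recovery instead.
* **Two p thresholds.** The DMP definition and the gene rule use separately
  configurable cuts (`dmp_q_threshold`, `gene_q_threshold`, both 0.01 on
  adjusted values by default) since the source analysis states them
  inconsistently (0.01 adjusted vs 0.05 unadjusted).
* **Strict inequality** at the gene rule's Δβ threshold: a probe at exactly
  0.35 does not qualify.
* **Outlier sensitivity.** A probe whose Δβ sits just under threshold with
  outliers retained can flip to well over threshold once a few
  opposite-extreme values are removed; the test suite constructs exactly
  this scenario (unfiltered Δβ ≈ 0.336, filtered 0.400) and asserts the
  flip.

## Comorbidity intersection and common markers

Diseases that co-occur with a cancer implicate genes relevant to it.
Per-comorbidity gene lists (exports from gene–disease databases, consumed
here as plain text) are unioned into a per-cancer **secondary** set;
candidates are `primary ∩ secondary`, keeping the primary Δβ values. A gene
is a **common marker** when it appears in *every* cancer's candidate set
with `|Δβ| > 0.2` in each. The cut uses the absolute value and sign
consistency is *not* required — a gene may be hypermethylated in one cancer
and hypomethylated in another; status is reported per cancer. The 0.2 cut
is applied to each cancer's candidate set before intersecting (the order is
ambiguous in the source; cutting first is the stricter reading and is
order-invariant anyway).

## The GO functional gene distance

Panels should span *different* biology; two markers with the same function
are redundant. The distance between genes is built from the GO DAG
(`is_a` edges only, three namespaces) plus gene→term annotations, with the
true-path rule applied first: a gene annotated to a term is propagated to
every ancestor. For a term *t* with propagated gene set *G_t*,

* weight: `W(t) = |G_t| / N`, with `N` the number of distinct annotated
  genes. Weights grow toward the root (propagation makes them monotone
  along edges), so a weight is a depth proxy: `W = 1` at a fully annotated
  root, small at specific leaves.
* information-content distance:
  `dist_IC(ti, tj) = 2 W(LCA) - W(ti) - W(tj)` where the LCA is the
  *minimum-weight* common ancestor (the most specific shared term; every
  term is its own ancestor). If the terms share no ancestor — different
  namespaces — `dist_IC = 1` exactly. Under propagation the expression is
  always ≥ 0, but it can exceed 1: two leaves of weight 0.1 directly under
  a weight-1 root are at `2 - 0.2 = 1.8`.
* Sørensen–Dice set distance:
  `dist_SC(ti, tj) = |G_ti Δ G_tj| / (|G_ti ∪ G_tj| + |G_ti ∩ G_tj|)`,
  0 for identical gene sets, 1 for disjoint ones.
* term distance: the arithmetic mean of the two components.
* gene distance: the mean of the term distance over the *full
  cross-product* of the two genes' directly annotated terms (not best-match
  averaging; the alternative of deduplicating shared terms is noted but the
  plain cross-product is what "averaging the distances between term pairs"
  says).

The gene–gene matrix has a forced zero diagonal, and is normalized only
when needed: if the maximum off-diagonal entry exceeds 1, all off-diagonal
entries are divided by it. Max-scaling (rather than min–max) preserves the
analytic anchors — a cross-namespace, disjoint-annotation pair stays at
exactly 1, and genes with identical annotations stay at 0. The triangle
inequality is *not* guaranteed by this construction and is not asserted
anywhere.

## Functional grouping and panel selection

The matrix is clustered with UPGMA (average linkage), implemented directly
so tie-breaking is deterministic: among equally close pairs, the pair with
the lexicographically smallest member label merges first, making the
dendrogram invariant to input order. The tree is cut into `n_groups = 3`
groups by default (no automatic cut-height selection — the group count is
the analyst's lever) and each group gets a medoid representative; the final
panel, however, is chosen by classification, not by trusting the medoid:

* every one-gene-per-group combination is enumerated (product of group
  sizes);
* each panel is evaluated per cancer with an RBF-kernel SVM on per-subject
  features — the beta-value of each panel gene's representative probe, the
  probe with the largest training-set |Δβ|. Probe choice, missing-value
  imputation (training median) and feature standardization are all computed
  on the training split only and reused verbatim on the test split;
* splits are stratified (80/20 by default) under a fixed seed; metrics are
  accuracy, recall, precision and F-score with tumor as the positive class.
  A test set with no normals is legal (flagged; recall degenerates to
  accuracy);
* the optimal panel maximizes mean test accuracy across cancers, ties going
  to fewer genes and then lexicographic order.

A universal model is also supported: one SVM trained on the pooled training
cancers, evaluated per held-out cancer.

**SVM implementation.** No SVM package is available in the target
environment, so the package ships a compact sequential-minimal-optimization
solver (RBF kernel, soft margin `C = 1`, `gamma = 1/(n_features · var(X))`,
balanced class weights via per-sample C). The working-set choice is
deterministic (max |E_i − E_j|), so a fixed seed yields bit-identical
reports. This is adequate for the data sizes the pipeline sees (hundreds of
subjects, ≤ tens of features); it is not a general-purpose SVM.

## The synthetic world

Everything the pipeline consumes can be generated with planted ground
truth (`sim_spec()`, `simulate_beta_matrix()`, `simulate_go()`,
`simulate_comorbidity_sets()`), so every stage is testable offline.

* **Beta-values** are Beta-distributed, parameterized by (mean, precision)
  — `shape1 = μφ`, `shape2 = (1−μ)φ` — because planted effects are then
  direct mean shifts. Default precision `φ = 50` gives a per-sample SD of
  ≈ 0.05–0.07, the spread of typical post-QC 450K groups. Null probes draw
  their common group mean from a low/intermediate/high mixture mimicking
  the genome-wide bimodal beta distribution. Planted probes shift the
  tumor mean by the signed effect (default +0.4 over a 0.15 baseline, i.e.
  a strong cancer promoter-hypermethylation signal); validation happens at
  spec construction so no sample is ever clipped. Default cohorts are
  30+30 — deliberately smaller than TCGA cohorts but large enough that a
  0.4 effect is unmissable, which is the point of a recovery test.
* **Outliers** replace a value with a draw near the opposite methylation
  extreme at rate 0.02 — the mechanism by which a few aberrant subjects
  drag Δβ under a threshold until IQR filtering removes them.
* **The synthetic GO** plants functional groups: genes in a group share
  one specific term per namespace (plus a private leaf each for depth);
  genes across groups share only namespace roots, which background genes
  keep at weight 1. Within-group distances are therefore small and
  between-group distances hit the normalized ceiling, so UPGMA at the true
  k recovers the planted partition exactly (asserted at adjusted Rand
  index 1 over 20 seeds for the 5/2/1 structure).
* **Panel-selection simulations** use three cancers of 100+100 subjects,
  a planted effect of 0.15 on exactly the genes of one
  one-per-group combination, and a 50/50 split. The effect size is chosen
  so single features are *partially* informative (single-feature accuracy
  well below 1), otherwise every combination saturates and the argmax is
  noise; the 50/50 split makes the test halves large enough to resolve the
  informative panel's advantage.

What a green synthetic test does **not** establish: robustness to batch
effects, cell-composition heterogeneity, probe cross-hybridization, the
true annotation-depth distribution of real GO, or performance at real
cohort imbalance. The generator emulates the statistical skeleton of the
analysis, not array chemistry.

## Degenerate inputs and numerical choices

* Quartiles use R's default type-7 interpolation; an IQR of zero collapses
  the fences to a point (identical values survive; anything else is
  removed), except at `k = Inf`, which is the identity by construction.
* Fewer than 4 finite values: the filter passes input through, flagged.
* Zero-variance groups in the Welch test resolve to p = 1 (equal means) or
  p = 0 rather than NaN.
* Tukey-fence filtering is not idempotent in general (fences can tighten on
  the reduced sample); it is idempotent when inliers are bounded away from
  outliers, which is the regime the per-probe filter targets.
* BH is the textbook step-up with enforced monotonicity, checked against an
  independent implementation on 1000 random vectors.
* `cut_groups` labels groups by their lexicographically smallest member;
  medoid ties also resolve lexicographically.
* The CLI run configuration is JSON rather than YAML (no YAML parser in the
  supported dependency set); the schema mirrors `meth_config()` exactly.

## Known limitations

Raw IDAT ingestion, array QC and BMIQ normalization are out of scope:
the package starts from preprocessed beta-matrices. Comorbidity gene lists
are consumed as files, not retrieved. KEGG/GSEA enrichment is out of scope.
`part_of` and other non-`is_a` GO relations are ignored; annotation
evidence codes are not filtered. No batch or cell-composition correction is
attempted.
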