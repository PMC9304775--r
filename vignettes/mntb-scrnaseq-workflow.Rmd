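---
title: "Methods: a marker-driven clustering workflow for small single-cell datasets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a marker-driven clustering workflow for small single-cell datasets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and shape

`scmntb` implements a complete analysis path for plate- or
microfluidics-scale single-cell RNA-seq of a small dissociated tissue —
on the order of two to three hundred deeply sequenced cells spanning a
handful of well-separated cell types, as in the early postnatal MNTB
(principal neurons, astrocytes, oligodendrocytes, vascular-associated
cells). Each stage is an exported function returning a classed S3 object,
and `run_pipeline()` chains them; users drive the package from R (or
`Rscript`), so no separate shell executable is shipped — the functions,
`pipeline_config()` and `scripts/acceptance.R` are the interface.

## Cell and gene quality control

Per-cell metrics are the number of detected genes and the fraction of
counts on mitochondrial genes. Outliers are removed at 3 median absolute
deviations (MAD, scaled by 1.4826 so that it estimates a normal SD):
two-sided for detected genes — both collapsed and suspiciously complex
libraries are suspect (the latter being potential multiplets) — but upper
tail only for mitochondrial fraction, since only high mitochondrial
content marks a damaged cell. Two deliberate conventions: a metric whose
MAD is zero produces no outliers (a constant metric must not drop every
cell), and manually annotated exclusions (e.g. doublets spotted on
capture-site images) are always removed; doublet status is never inferred
automatically.

Gene filtering drops all-zero genes and keeps genes with at least 10
counts in at least 3 cells. A fourth-quartile restriction (top 25% of
survivors by mean expression) is implemented but off by default: the two
published rules can be read as alternatives or as a chain, so both
readings are preserved behind the `quartile_filter` flag. Filters operate
on raw counts; normalization comes after.

## Normalization

Per-cell size factors use the pooling/deconvolution strategy: cells are
ordered on a ring by library size; for each pool size
k ∈ {20, 40, 60, 80, 100} (capped at half the cell count) and each window
of k consecutive cells, the pooled count vector is compared to the
average pseudo-cell by the median of gene-wise ratios (genes with
pseudo-cell mean below 1 excluded). Each window contributes one equation
Σ_{c∈window} θ_c = r_window; weakly weighted per-cell anchors
(θ_c ≈ library-size factor, weight 0.01) make the stacked system full
rank, and least squares plus rescaling to unit mean gives the factors.
Pooling cancels the stochastic zeros that bias per-cell median-ratio
estimators at this depth. Non-positive solutions (possible only in
pathological inputs) are clipped to the smallest positive estimate with a
warning.

Expression values are log₂(CPM + 1) with effective library size
θ_c × (mean total count across cells). The CPM denominator is a
convention we fixed ourselves: tying it to the mean total count keeps CPM
on the familiar per-million scale while remaining consistent with the
factors. Pseudocount 1 on the CPM scale maps zero counts to exactly 0,
matching how log-CPM violin plots are usually drawn. On
identical-composition data the deconvolution factors reduce to
library-size factors, which the tests verify.

## Variable-gene selection

The mean–variance trend of log₂ CPM is fitted by robust local-linear
LOESS (span 0.3 by default; the fitted trend is floored at 1e−8). The
trend is read as the technical variance expected at a given mean, and
each gene's ratio var/trend is tested one-sided with
(n−1)·var/trend ~ χ²(n−1) — our choice of reference distribution, since
the published workflow states only an FDR. Genes with ratio > 2 at BH
FDR < 0.05 are candidates. Constant genes get ratio 0, p = 1.

Candidates then pass a Spearman correlation filter: rank correlations for
all candidate pairs, p-values from one pooled permutation null (the
correlation of two independently shuffled rank vectors, 10,000 draws by
default, shared across pairs), BH across pairs; a gene survives iff it
joins at least one pair with |ρ| > 0.4 at FDR ≤ 0.001. Being rank-based,
the filter is invariant to monotone per-gene transforms. One numerical
consequence of the pooled null is a granularity floor: the smallest
attainable p is 1/(n_perm+1), so with few tested pairs the BH-adjusted
values cannot reach very small FDR targets; with the default 10,000
permutations and the pair counts the pipeline produces this is never
binding, but analyses of very small candidate sets should raise `n_perm`.
The reporter transcript is removed before any of this: it tracks lineage,
not biology, and would otherwise dominate the feature space.

## Clustering and iterative refinement

Cells are clustered on per-gene median-centered log₂ CPM — the quantity
heatmaps display — with Ward linkage on Euclidean distances (the linkage
is the published choice; the distance is ours, matching the displayed
space). The tree is cut at the largest number of clusters k such that
(a) every cluster has at least 5 cells and (b) the cut separates real
structure: the merge height joining two of the k clusters must exceed
`gap_min` (default 1.3) times the tallest merge inside them. The guard in
(b) is a deliberate design choice: the size constraint alone lets Ward
slice homogeneous populations into arbitrary balanced subclusters,
because within-population merge heights grow smoothly; between distinct
populations the dendrogram jumps (on the bundled synthetic data the jump
ratio at the true partition is ≈ 4 versus ≤ 1.2 for noise splits, so the
default sits well between the two regimes). Data without structure yield
a single cluster. `k` can also be fixed explicitly for reproduction runs.
Ties in the dendrogram follow `stats::hclust`'s deterministic merge
order.

Refinement then alternates clustering and differential expression: all
pairwise NB contrasts between current clusters at the standard gates
(≥ 2-fold, FDR ≤ 0.05, detected at ≥ 5 CPM in ≥ 20% of either cluster)
define the next feature set (the union of significant genes), and the
loop stops when the partition — compared permutation-invariantly — no
longer changes, or after `max_iter` (10) rounds as a cycling guard;
convergence on well-separated data takes two rounds. An empty DE gene set
stops the loop with a warning and keeps the last stable result. Manual
exclusion lists can be applied between rounds.

## Differential expression

Contrasts (pairwise, or one group against the rest, optionally after
merging similar clusters such as the two neuronal ones) are per-gene NB
likelihood-ratio tests: group means fitted by Fisher scoring on the log
scale with offsets log(effective library size), deviance referred to
χ²(1), BH FDR within each contrast. Dispersions are method-of-moments
estimates from depth-normalized within-group counts, pooled across
groups by degrees of freedom, and shrunk 70% toward a robust LOESS trend
over mean expression; all-zero genes inherit the trend value. This
explicit test is the package's own machinery — a documented stand-in
calibrated by simulation (null type-I error ≈ 0.05; planted 8-fold
markers recovered at > 90%), not a byte-level clone of any published
tool, though its rankings agree closely with an exact-test reference in
the cross-check tests.

Reported fold changes deliberately come from the ratio of average CPM
between the groups, independent of the fitted model, because that is the
reporting convention of the tables the workflow mirrors; when either
average is zero a continuity constant (0.5 CPM) is added to both sides,
keeping A-vs-B and B-vs-A exactly reciprocal, and the gene is flagged.
Published tables of this kind are ambiguous about whether a printed
"fold change (log₂)" is a ratio or its logarithm; the `de_table`
therefore carries both `fold_change` and `log2_fc`, and downstream code
must not assume either reading.

## Annotation, reporter validation, signaling edges

Cluster identity is scored per (cluster, type) as the mean over the
type's markers of (cluster mean log₂ CPM − grand mean), assigning the
argmax; exact ties are flagged ambiguous rather than silently broken, and
marker genes missing from the matrix warn (a type with no resolvable
markers is reported unassignable). Neuronal assignments are validated
against the reporter transcript — kept in the matrix though excluded from
clustering — by one-sided Wilcoxon rank-sum tests of each neuronal
cluster against pooled non-neuronal cells, BH-adjusted, passing at
adjusted p ≤ 0.005 (exact enumeration at small sizes without ties, the
tie-corrected normal approximation otherwise).

Ligand–receptor directionality freezes the narrative reading of violin
plots into an explicit rule: an edge sender→receiver is emitted when the
ligand passes the enrichment rule in the sender's one-vs-rest table and
the receptor passes it in the receiver's (default: the DE gates;
"expressed" mode requires only within-cluster detection). Edges are
descriptive summaries of enrichment, never significance statements about
signaling; unresolvable gene identifiers are listed, not dropped
silently.

## Imaging quantification statistics

`percent_positive_area()` models background as a grayscale morphological
opening with a flat disc structuring element of the given radius
(default 25 px), subtracts it, clips at zero, and reports the percentage
of suprathreshold pixels inside the ROI. The opening contract — a flat
background plus any feature smaller than the disc is removed exactly, and
the operation is idempotent — is what the tests pin down; pixel parity
with any particular GUI tool is a non-goal. Whether thresholds apply to
raw or subtracted intensities differs between experiments, so the setting
is recorded in the result rather than guessed. `volume_fraction()` is the
plain voxel-count ratio (voxel dimensions cancel). `bky_two_stage()`
implements the adaptive two-stage FDR: BH at q/(1+q), estimate the null
count m0 from the non-rejections, rerun BH at q·m/m0; it never rejects
less than plain BH once stage one rejects anything. `welch_bky()` pairs
it with unequal-variance t tests, the appropriate default when group SDs
differ; both call the standard test implementations.

## The synthetic generator

`generate_dataset()` draws counts NB(mean = L_c · r_g, dispersion α) with
variance μ + αμ² — α scalar 0.1 by default, a single realistic knob —
where L_c is a log-normal per-cell depth multiplier and r_g the cell
type's rate vector with markers multiplied by `marker_fold`. The default
configuration mirrors the study conditions the pipeline targets: five
populations (N1 60, N2 50, astrocytes 50, oligodendrocytes 40, VACs 40 —
240 cells, within the published 200–300 range with the same type
ordering by abundance), 8-fold markers carrying the field's marker
symbols plus planted signaling genes (Fgf9 neuronal, Fgfr3 astrocytic,
VEGF/TGFβ receptors in VACs, Notch components in glia and VACs), a
highly expressed tdTomato reporter restricted to neuron profiles
(leakage configurable, 0 by default, since observed leakage is reported
as negligible), 10 mitochondrial genes at ~3% of baseline counts, and
depth log-sd 0.3. The published run does not state per-cell depth or
dispersion, so depth meanlog log(5·10⁴) over a 2,000-gene universe was
chosen once as a desk-scale stand-in that reproduces the qualitative QC
behavior (tight detected-genes distribution, few-percent mitochondrial
fractions); absolute genes-per-cell numbers are not comparable to a
whole-transcriptome run and are not asserted anywhere.

`inject_artifacts()` emulates what QC must catch: low-quality cells are
binomially downsampled to 20% of their total and their mitochondrial
share inflated to ≥ 50% by a multinomial redraw that preserves the
downsampled total (keeping totals interpretable); doublets are exact
element-wise sums of two random parents, appended with both parent types
recorded. What the generator does **not** emulate: batch effects across
capture plates, ambient RNA, gene–gene correlation beyond cell-type
structure, zero inflation beyond NB sampling, and transcript-length
effects. Passing recovery tests on this generator therefore demonstrates
the pipeline's statistical machinery under its stated model, not
robustness to every artifact of real tissue dissociation.

## Problem sizes and determinism

The bundled analyses run at desk scale by design: 240-cell / 2,000-gene
pipeline runs (seconds), 100–200-cell simulations for normalization and
DE calibration, 10,000-draw permutation and replicate nulls. All
randomness in a pipeline run flows from the single `seed` in
`pipeline_config()` / `simulation_config()`; reruns are bit-identical,
which the tests assert.

## Known limitations

The dispersion shrinkage weight (0.7) and LOESS spans are sensible
defaults, not estimated empirical-Bayes quantities; the χ²(1) reference
for the LRT is asymptotic and mildly liberal for very small clusters
(bounded in the calibration tests); the correlation filter's pooled null
ignores between-gene dependence, which is conservative for the kept-gene
decision; the tree-cut guard `gap_min` trades a small risk of merging
genuinely similar subtypes (lower it to split more finely) against noise
fragmentation; and marker-based annotation is only as good as the marker
sets supplied.
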