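# scmntb

Single-cell RNA-seq clustering and intercellular-signaling analysis for
small dissociated-tissue datasets, built around the cell populations of
the early postnatal medial nucleus of the trapezoid body (MNTB) — an
auditory brainstem nucleus whose near-homogeneous principal neurons,
astrocytes, oligodendrocytes and vascular-associated cells (VACs) make it
a clean model system for studying neural tissue maturation. The package
is aimed at analysts working with plate/microfluidics-scale experiments
(a few hundred deeply sequenced cells) who want every stage of a
marker-driven hierarchical clustering workflow to be explicit, scriptable
and testable against ground truth.

## What it computes

Starting from a genes × cells integer count matrix, `run_pipeline()`
chains:

1. **Cell QC** — per-cell detected genes and mitochondrial fraction;
   outliers beyond 3 median absolute deviations are removed (two-sided on
   detected genes, upper tail only on mitochondrial fraction; MAD with
   the 1.4826 consistency constant).
2. **Gene filtering** — drop all-zero genes; keep genes with ≥ 10 counts
   in ≥ 3 cells (optional fourth-quartile restriction by mean
   expression).
3. **Normalization** — pooled deconvolution size factors: cells are
   arranged on a ring by library size; each window of k consecutive cells
   is pooled and compared with the average pseudo-cell by the median of
   gene-wise ratios, giving linear equations Σ_{c∈pool} θ_c = r_pool that
   are solved by least squares and rescaled to mean 1. Expression becomes
   log₂(CPM + 1) with effective library size θ_c · mean(total counts).
4. **Variable-gene selection** — LOESS fit of per-gene variance against
   mean log₂ CPM; genes with variance ratio > 2 at BH FDR < 0.05 under a
   scaled-χ² model ((n−1)·var/trend ~ χ²(n−1)), then a Spearman
   correlation filter (pooled permutation null; keep genes in ≥ 1 pair
   with |ρ| > 0.4 at FDR ≤ 0.001). The reporter transcript (tdTomato) is
   removed from the feature space first.
5. **Clustering** — Ward-linkage hierarchical clustering on Euclidean
   distances over median-centered log₂ CPM, cut at the most granular
   partition whose clusters all have ≥ 5 cells and whose merges separate
   real structure; then iterative refinement: all pairwise
   negative-binomial contrasts (≥ 2-fold, FDR ≤ 0.05, detected at ≥ 5 CPM
   in ≥ 20% of either cluster) define a new gene set, and clustering
   repeats until the partition stops changing.
6. **Differential expression** — per-gene NB likelihood-ratio tests with
   trended, shrunken method-of-moments dispersions (variance μ + αμ²);
   fold changes are ratios of average CPM, the convention used for
   reporting.
7. **Annotation and validation** — clusters scored against marker sets
   (neurons: Calb1/Gabra5/Grin2a; astrocytes: Aldh1l1/Slc1a2/Slc1a3;
   oligodendrocytes: Cnp/Mbp/Sox10; VACs: Cldn5/Flt1/Pdgfrb); neuronal
   identity cross-checked by a one-sided Wilcoxon rank-sum test on
   reporter CPM (pass at adjusted p ≤ 0.005).
8. **Directional signaling** — ligand–receptor pairs (FGF, VEGF, TGFβ,
   Delta-Notch) emit a descriptive sender→receiver edge when the ligand
   is enriched in one cluster and the receptor in another.

A synthetic-data module (`generate_dataset()`, `inject_artifacts()`)
draws NB counts with planted cell types, marker folds, a neuron-restricted
reporter, log-normal depths, low-quality cells and doublets, so each
stage can be tested against known truth. `percent_positive_area()`,
`volume_fraction()`, `bky_two_stage()` and `welch_bky()` implement the
imaging quantification arithmetic and the Benjamini–Krieger–Yekutieli
two-stage FDR (q = 1%) used for validation experiments.

## Worked example

```r
library(scmntb)
ds  <- generate_dataset(default_simulation_config(seed = 7))
rep <- run_pipeline(ds, pipeline_config(seed = 7))
print(rep)
```

```
[scmntb] QC: kept 232 / 240 cells
[scmntb] gene filter: kept 1766 / 2000 genes
[scmntb] normalization: size factors in [0.50, 2.04]
[scmntb] HVG: 82 variable genes
[scmntb] correlation filter: 82 -> 81 genes
[scmntb] clustering: 5 clusters after 2 round(s), converged: TRUE
[scmntb] annotation: 1=Neuron, 2=Neuron, 3=Astrocyte, 4=Oligodendrocyte, 5=VAC
[scmntb] DE: Astrocyte: 90, Neuron: 90, Oligodendrocyte: 88, VAC: 88
[scmntb] reporter validation: pass (max adjusted p 5.3e-38)
[scmntb] signaling: 3 directed edges
run_report
  cells: 240 -> 232; genes: 2000 -> 1766
  HVGs: 82 (-> 81 after correlation filter)
  clusters: 60/49/49/37/37 (after 2 refinement round(s), converged TRUE)
  annotation: 1=Neuron, 2=Neuron, 3=Astrocyte, 4=Oligodendrocyte, 5=VAC
  reporter validation: pass
  ARI vs ground truth: 1.000
  ligand-receptor edges: 3
```

Eight of 240 cells fail QC (the simulated low-quality fraction is zero
here, so these are ordinary MAD-tail cells), the five planted populations
are recovered exactly (adjusted Rand index 1.0) in two refinement rounds,
both neuronal clusters validate against the reporter transcript, and the
planted Fgf9→Fgfr3 neuron→astrocyte edge appears among the directed
signaling edges.

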