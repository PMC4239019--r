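# devalign

Aligning medulloblastoma molecular subgroups to a developmental continuum
of reference expression profiles.

Medulloblastoma, the most common malignant paediatric brain tumour,
comprises four consensus molecular subgroups — WNT, SHH, Group 3 and
Group 4 — with molecular features suggestive of distinct cells of origin.
One way to localise each subgroup on the neuro-developmental timeline is
to compare tumour transcriptomes against reference profiles of normal
neural cell types ordered by developmental stage: CD133+ neural stem
cells (NSC), CD133− neural progenitors (NPC), fetal germinal matrix
(NFGM, ~week 16) and pooled fetal brain (NFB, weeks 22–33; a single
pooled profile, n = 1). `devalign` implements that analysis as a tested,
reusable pipeline for probe-set-level expression matrices, and ships a
seeded synthetic-cohort generator with planted ground truth so that every
stage can be validated without external downloads.

## The analysis

For an expression matrix X (genes × samples, log2 intensities) with
tumour subgroups S and ordered control groups C₁…C_K:

* **Preprocessing.** Quantile normalization (every column is mapped onto
  the mean order statistics); a detection-limit filter removing genes
  whose maximum *linear*-scale intensity is below 200 units; a network
  prefilter dropping cross-hybridizing `*_x_at` probe sets and
  low-variance genes.
* **Classification.** Query samples are projected into a PCA space fitted
  on a labelled reference cohort restricted to a classifier gene panel
  (the shipped default is a 24-gene subgroup panel of which typically 20
  are present on U133A-style arrays), and assigned the label of the
  nearest reference centroid in the leading components.
* **Centroid alignment.** PCA of the full cohort; group centroids on a
  configured component subspace (default PC 1, 2, 4); the centroid
  distance `d(g, h) = ‖c_g − c_h‖₂` ranks the controls by proximity to
  each tumour subgroup.
* **Developmental intersect analysis (DIA).** Per-gene two-sided
  Student's t tests of each subgroup against every multi-sample control
  (p < 0.05), with linear fold change `2^(Δ log2 mean)`. The n = 1
  control (NFB) is handled by the σ-fold membership rule:
  `σfold = (x_ref − mean_S)/sd_S`, outside the subgroup distribution when
  `|σfold| > k` (k = 2). A step-wise intersection then classes each gene
  per subgroup as **exclusive** (`$`: significant in the same direction
  versus *every* multi-sample control, and in no other subgroup),
  **shared** (`∧`), or none; n = 1 controls corroborate but cannot veto.
* **Co-expression network.** Unsigned weighted network `a_ij = |r_ij|^β`
  with β selected by scale-free topology fit; modules by average-linkage
  clustering of topological-overlap dissimilarity (1 − TOM) with a static
  tree cut; module eigengenes (unit-norm first singular vector of the
  standardized module submatrix); eigengene cluster families;
  subgroup-membership trait correlations; and **alignment-order
  scoring** — every injective map of the 4 subgroups onto the 4 control
  stages induces a per-sample stage trait, each eigengene is Pearson-
  correlated with it, and hypotheses are ranked by the best module
  correlation.
* **Enrichment.** One-sided hypergeometric over-representation of the
  exclusivity sets against user-supplied GMT collections, with BH
  adjustment; the universe is the detection-filtered gene set.

## Worked example

```r
library(devalign)

sim <- simulate_cohort(cohort_design(), simulation_params(seed = 1))
sim$matrix
#> ExpressionMatrix: 1200 genes x 74 samples (log2 scale)
#> groups: Group 3 (n=22), Group 4 (n=14), NFB (n=1), NFGM (n=2), NPC (n=3),
#>         NSC (n=3), SHH (n=21), WNT (n=8)

det <- detection_filter(sim$matrix)
det$report
#> FilterReport: 1200 genes in; 101 below detection, 0 suffix-removed,
#> 0 low-variance; 1099 retained

# developmental intersect analysis: subgroup-exclusive over-expression
calls <- stepwise_exclusive(dia_comparisons(det$matrix))
vapply(c("WNT", "SHH", "Group 3", "Group 4"),
       function(s) length(exclusive_genes(calls, s)), 0L)
#>     WNT     SHH Group 3 Group 4
#>      25      25      25      71

# centroid alignment in PC 1, 2, 4: nearest control per subgroup
ord <- pca_ordination(det$matrix)
ct <- group_centroids(ord, c(1, 2, 4))
vapply(ct$control_ranking, `[`, "", 1)
#>     WNT     SHH Group 3 Group 4
#>   "NSC"   "NPC"  "NFGM"   "NFB"

# co-expression network and alignment-order ranking
pre <- network_prefilter(det$matrix)
mod <- detect_modules(pre$matrix, power = 6)
eg  <- module_eigengenes(pre$matrix, mod)
head(score_alignment_orders(eg, pre$matrix)[, c("map", "score")], 3)
#>                               map     score
#> 1 WNT=1,SHH=2,Group 3=3,Group 4=4 0.8500294
#> 2 WNT=2,SHH=1,Group 3=3,Group 4=4 0.7596350
#> 3 WNT=1,SHH=2,Group 3=4,Group 4=3 0.7318914
```

The cohort was simulated with subgroups planted at stages 1–4; each
stage of the analysis recovers that structure: the 25 planted markers
per subgroup are called exclusive (Group 4's extra calls are gradient
genes that no multi-sample control at its stage can veto — NFB, the
stage-4 control, is a single profile), every subgroup's nearest centroid
is its planted control, and the true subgroup→stage map ranks first of
all 24 candidate orders with the best module correlation r = 0.85.

The same stages run end to end, from a YAML config or defaults, with a
TSV/Newick report bundle:

```r
run_pipeline(validate_config(config = list(out_dir = "out", seed = 1)))
```

or from a shell via the thin wrapper
`Rscript inst/cli/devalign.R run --seed 1 --out out`.

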