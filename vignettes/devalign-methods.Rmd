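---
title: "Methods: developmental alignment of tumour expression subgroups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: developmental alignment of tumour expression subgroups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(devalign)
```

# The problem

Medulloblastoma splits into four molecular subgroups (WNT, SHH, Group 3,
Group 4) whose transcriptomes resemble normal neural cell types at
different points of early human neurogenesis. `devalign` operationalises
that comparison: given a probe-set-level expression matrix containing
tumour subgroups and a series of control groups ordered by developmental
stage — here neural stem cells (NSC, stage 1), neural progenitor cells
(NPC, stage 2), fetal germinal matrix (NFGM, stage 3) and pooled fetal
brain (NFB, stage 4) — it asks which control each subgroup sits closest
to, which genes distinguish each subgroup from *all* controls, and which
ordering of subgroups along the stage axis the co-expression structure
supports.

All expression values are log2 intensities. The one deliberately
linear-scale rule is the detection limit: a gene whose maximum linear
intensity (`2^x`) across all samples stays below 200 units is treated as
unexpressed and removed before any query. Using the maximum (rather
than, say, the mean) keeps genes detected in any single group, which is
what per-subgroup over-expression queries need.

# Stages and their assumptions

## Normalization

`quantile_normalize()` forces every sample onto the mean order
statistics (the cross-array component of RMA, applied at probe-set
level). It assumes samples share a common intensity distribution, so
genuine global shifts — e.g. a strong expression gradient affecting many
genes in one group — are partly absorbed. On simulated cohorts, where a
planted stage gradient violates this assumption by construction,
normalization measurably attenuates the gradient; the validation runs
therefore operate on the simulated log2 matrix directly (it is already
on a common scale), while the pipeline default keeps normalization on,
as appropriate for real array data.

## Subgroup classification

`classify_by_reference()` fits a PCA on a labelled reference cohort
restricted to a classifier gene panel, projects query samples into that
fixed space (the reference geometry is never refitted), and assigns the
label of the nearest reference-group centroid (Euclidean, first
`n_components = 4` components — four being the number of discriminative
components in this setting). Nearest-centroid assignment is a declared
design choice: "alignment to a reference cohort" does not by itself
define an assignment rule, and the centroid rule is deterministic,
label-permutation equivariant, and invariant to global intensity
shifts. Panel genes absent from either cohort are dropped with a counted
warning (on U133A-style arrays, 4 of the shipped 24-gene panel are
typically missing). Probabilistic assignments are out of scope.

## Centroid alignment

`pca_ordination()` centres genes and decomposes the sample covariance;
variance fractions are eigenvalue ratios and sum to one.
`group_centroids()` takes means of the score vectors per group on a
configured component list and computes all pairwise Euclidean distances
("geometric vector length" between group centres). The default
component list `c(1, 2, 4)` is configuration, not an automatic choice:
in the subgroup-alignment setting the third component separates
neoplastic from non-neoplastic samples rather than subgroups from
controls, and its exclusion is an interpretive judgement the pipeline
records but does not automate. Metric axioms (symmetry, non-negativity,
triangle inequality) are asserted on every distance table.

## Developmental intersect analysis

For every (subgroup, control) pair with control n ≥ 2,
`pairwise_test()` computes per-gene two-sided t tests — pooled-variance
Student by default, Welch by flag — with significance at α = 0.05 and
linear fold change `2^(Δ log2 mean)`. No multiple-testing correction is
applied by default, matching the raw p < 0.05 convention of the original
analysis style; `p.adjust`-based correction can be layered on the
returned tables. Degenerate genes (zero variance in both groups, equal
means) report t = 0, p = 1 by convention.

The single-profile control (NFB) cannot support a t test. Instead,
`single_reference_membership()` measures the σ-fold deviation
`(x_ref − mean_S)/sd_S` and calls the reference *outside* the subgroup
distribution when `|σfold| > k`, with k = 2 by default (the membership
rule is stated in terms of standard deviations; the cutoff value itself
is configurable because only the rule, not k, is canonical). A reference
more than k·sd *below* the subgroup mean means the subgroup is
over-expressed relative to it. Under a null where the reference is drawn
from the subgroup's own distribution, the outside rate has the closed
form `2·P(T_{n−1} > k/√(1+1/n))`, which the tests verify by simulation.

`stepwise_exclusive()` then applies the intersect rule per gene and
subgroup S: step 1 requires significance in the stated direction against
*every* control with n > 1; single-sample controls contribute an
"outside, same direction" corroboration flag but are not required — they
cannot veto. Step 2 marks step-1 passers `exclusive` if no other
subgroup also passed (the `$` class) and `shared` otherwise (`∧`). At
most one subgroup can hold `exclusive` for a gene. Note one subtlety:
tightening α shrinks the step-1 pass sets monotonically, but a shared
gene can *become* exclusive at a smaller α when only its competitor
drops out; the monotone object is the pass set, and that is what the
property tests assert.

## Co-expression network

`adjacency_matrix()` uses `|cor|^β` (unsigned, the default — signedness
is configurable because either convention is defensible) and
`select_soft_power()` picks β by the scale-free topology criterion: bin
the connectivity distribution, regress log10 frequency on log10 bin
centre, and choose the smallest β whose R² reaches the target (0.85),
else the argmax. Two caveats are deliberate: a degenerate connectivity
distribution yields an undefined fit and a warned fallback; and data
whose correlation structure is dominated by a few dense planted modules
is *not* scale-free, so on synthetic cohorts no β reaches the target and
the argmax becomes an unstable boundary pick. The pipeline therefore
falls back to the conventional default power for the network type (6
unsigned, 12 signed) whenever the target is unattained, and logs that
decision.

`detect_modules()` clusters genes by average linkage on 1 − TOM
(topological overlap) and cuts the tree at a *static* height — simpler
and fully deterministic, in contrast to dynamic hybrid cutting. The
default cut height 0.7 was fixed after inspecting TOM-dissimilarity
distributions on simulated cohorts: within-module joins fall well below
it and between-module joins above it across the working range of soft
powers. Clusters smaller than `min_module_size = 20` become label 0
(unassigned). Module labels are ordered by size; the partition (not the
arbitrary label values) is invariant to gene order.

`module_eigengenes()` returns, per module, the unit-norm first right
singular vector of the row-standardized member submatrix — the
normalized linear combination of member genes with the largest variance
— signed so that mean correlation with the members is non-negative.
`cluster_families()` groups modules by average linkage on eigengene
correlation distance. `trait_association()` correlates eigengenes with
0/1 subgroup-membership traits, with two-sided p from the t
approximation on n − 2 degrees of freedom (a permutation check of its
calibration is part of the validation suite).

## Alignment-order scoring

`score_alignment_orders()` enumerates all injective maps of the tumour
subgroups onto the control stages (4! = 24 by default). Each map induces
a per-sample trait: control samples keep their own stage, tumour samples
get their subgroup's mapped stage. Each eigengene is Pearson-correlated
with the trait and the hypothesis score is the best module correlation —
the single most descriptive genetic neighbourhood, rather than an
average over modules. Two encodings of the trait exist because "mean
intensity of developmental controls in alignment order" can be read two
ways: `stage_rank` (default) uses the stage indices 1..K;
`control_mean` substitutes each stage's control-group mean log2
intensity. By default the score is the maximum *signed* correlation:
requiring positive correlation with the stage order breaks the
reversal ambiguity (with `positive_only = FALSE` the score is max |r|
and a reversed order can tie). Control samples anchor their own stages
under every candidate map, so a reversed map is not a global sign flip
of the trait and scores strictly below the true order even in the
noise-free limit.

## Over-representation

`overrepresentation()` is a transparent surrogate for proprietary
pathway tools: one-sided hypergeometric tests of a query set against a
GMT collection, equivalent to one-sided Fisher tests on the 2×2 table,
with BH adjustment reported alongside raw p. The universe is the
detection-filtered gene set — mirroring the below-detection exclusion
applied before any DIA query — not the array's full probe list.
Proprietary knowledge-base p-values are not comparable and are not a
reproduction target.

# The synthetic cohort generator

`simulate_cohort()` draws log2 intensities under a generative model
with three planted structures, at the study's design scale by default:
control groups NSC (n = 3), NPC (n = 3), NFGM (n = 2), NFB (n = 1) at
stages 1–4 and tumour subgroups WNT (n = 8), SHH (n = 21), Group 3
(n = 22), Group 4 (n = 14) planted at stages 1–4; 1200 genes.

* **Gradient modules** (5 modules × 40 genes): gene g in module m has
  value `baseline_g + loading_g · (slope · stage_s + activity_m(s)) +
  noise`, with `loading_g ~ N(1, 0.2)`, per-sample module activity
  `activity_m(s) ~ N(0, 1)` and slope 1.5 log2 units per stage step.
  The expected value is exactly `baseline + slope × stage` (controls use
  their stage, tumours their planted stage). The activity term is what
  makes the five modules mutually distinguishable: without it they would
  share a single expected pattern and no clustering method could
  recover a five-module partition. Setting all sd parameters to zero
  gives the exact noise-free limit in which module genes are affine in
  stage and the true alignment order scores r = 1.
* **Exclusive markers** (25 per subgroup, disjoint from modules and from
  each other): `+marker_effect` (2 log2 units, i.e. 4-fold) only in the
  owning subgroup's samples.
* **Below-detection genes** (10% of the background): baselines drawn so
  every expected linear intensity is below 200 units.

Everything else is i.i.d. baseline `N(8, 1)` plus `N(0, 0.5)` noise.
Defaults were chosen once for realism at array scale — baselines around
2⁸ = 256 linear units, noise of half a log2 unit, 4-fold marker effects
— and effect sizes are testability choices, not estimates of any real
cohort. Identical seeds give bit-identical cohorts.

What the generator does *not* emulate: probe-level (CEL) structure,
batch or platform effects, copy-number-driven expression,
heavy-tailed noise, correlated background genes, or cohort-specific
probe counts. Passing the validation suite therefore demonstrates the
correctness and calibration of the machinery under its stated model,
not the biological conclusions obtainable from any real cohort.

One evaluation subtlety follows from the model itself: gradient-module
genes are genuinely over-expressed versus every *multi-sample* control
for the top-stage subgroup, because the stage-4 control (NFB) is a
single profile and by the intersect rule cannot veto. Calling them
exclusive there is correct behaviour, so marker precision/recall is
evaluated on the non-gradient gene set; module recovery is scored
separately via the adjusted Rand index and the alignment ranking.

# Validation suite and problem sizes

The test suite validates each operation against independent oracles
(`t.test`, covariance eigendecompositions, brute-force rank maps,
triple-sum TOM, exhaustive hypergeometric tail sums, exhaustive
enumeration of exclusivity patterns) and then measures recovery of the
planted truth at design scale: exclusive-marker precision/recall over
50 seeded cohorts, module recovery (ARI) over 20, alignment-order
ranking over 100 (plus noise-free runs), nearest-control centroid
recovery over 100, held-out classifier accuracy, permutation
calibration of trait association with 10⁴ draws, and byte-identical
reproduction of the full pipeline under a fixed seed. These replicate
counts keep the whole suite under a minute on one CPU while holding
Monte-Carlo error on the reported rates to a few percent.
`scripts/acceptance.R` recomputes the same quantities from scratch for
any seed and writes them as JSON.

# Numerical choices and degenerate inputs

* Ties in the variance prefilter break deterministically by gene id;
  filters preserve input gene order; each removed gene is counted once,
  by the first filter that removed it.
* Fixture round-trips are lossless: expression values serialize with 17
  significant digits.
* Zero-variance genes in a t test: t = 0, p = 1 when means are equal,
  p = 0 otherwise. Zero-sd subgroups in the membership test: decided by
  exact equality, else outside.
* A constant expression matrix has no principal components and is
  rejected; a constant trait yields NA correlations rather than errors.
* Degenerate scale-free fits (all connectivities equal, or fewer than 3
  usable histogram bins) are NA with a warned fallback.
* Down-regulated fold changes render with the signed convention
  −1/ratio, so a ratio of 0.25 prints as −4.
* The pipeline excludes the output directory from the configuration
  hash, so identical configurations reproduce byte-identical bundles in
  different locations; a stage failure writes a `FAILED` marker naming
  the stage and keeps completed outputs.

# Limitations

* The assignment rule ("nearest centroid in PC space") and the
  membership cutoff k = 2 are declared operationalizations of
  under-specified conventions; both are configurable.
* Static tree cutting trades sensitivity for determinism; cohorts with
  nested or weak module structure may warrant dynamic cutting outside
  this package.
* The alignment-order score uses the best single module; a mean- or
  family-level score would weight evidence differently.
* Reproducing cohort-specific quantities (probe counts surviving
  filters, named-gene fold changes, proprietary pathway p-values)
  requires the original cohorts and is out of scope; the validation
  suite is property-based by design.
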