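---
title: "Methods: network subtyping of CSF proteomic cohorts"
author: "CSFSubtypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network subtyping of CSF proteomic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

CSFSubtypes implements an end-to-end pipeline for molecular subtyping of
cerebrospinal fluid (CSF) proteomes measured by multiplexed mass
spectrometry: batch harmonization, signed co-expression network analysis,
modularity-based sample subtyping, cross-cohort subtype transfer, and
dose-response analysis of plasma spiked into CSF. Every stage operates on a
`SummarizedExperiment` whose assay is a log2 protein-by-sample abundance
matrix with missing values allowed, and whose `colData` carries sample
traits (set and batch labels, pooled-reference flags, diagnosis, race, sex,
age, immunoassay biomarkers, replicate-pair links).

The package also ships a synthetic cohort generator so the whole pipeline is
testable without any external download. The generator is a first-class,
tested component, and its defaults define the study conditions used by the
test suite and the acceptance script.

# The synthetic cohort generator

The generative model is additive Gaussian on the log2 scale. Protein $p$ in
module $m$ for sample $s$ is

$$x_{ps} = b_p + \lambda_p f_{m(p),s} + \beta_{b(s),p} + \varepsilon_{ps},$$

with protein baseline $b_p \sim N(0, 0.5^2)$, loading
$\lambda_p \sim N(1, 0.3^2)$, per-(batch, protein) offset
$\beta \sim N(0, 0.4^2)$ and residual noise
$\varepsilon \sim N(0, 0.5^2)$. The module factor score
$f_{m,s} \sim N(0,1)$ is shifted by the sample's subtype and by
module-linked covariate effects (diagnosis, race, sex, age). This is the
simplest structure in which bicor modules, median-polish batch offsets and
subtype mean shifts are all recoverable, which is exactly what the
downstream stages must demonstrate.

Defaults describe the standard study-sized cohort: 400 samples by 1000
proteins; 10 modules of 200 down to 30 proteins with 160 background
proteins; 6 subtypes; 2 sets of 4 batches each with one pooled
global-internal-standard (GIS) channel per batch; 20 same-case replicate
pairs re-measured as Set 2; 10 percent missing cells.

Design choices worth stating explicitly:

* **Subtype shift pattern.** Subtype $t$ raises module $t$ and lowers module
  $t+1$ (cyclically over the first six modules) by 3 log2 units on the
  factor scale. The cyclic adjacent-pair design means distinct modules share
  at most *negative* factor correlation, so a signed network never merges
  them; an amplitude of 3 puts the planted subtypes in the cleanly separated
  regime (nearest-centroid accuracy on hub features above 99 percent),
  which is the setting in which the clustering contract (adjusted Rand index
  at least 0.8 over the full grid search) is meaningful.
* **Diagnosis effect.** +0.8 on module 2 and -0.8 on module 5 (log2, factor
  scale). A one-sided disease signature shifts every sample's median and is
  then partly absorbed by the median polish's sample sweep; an up/down
  signature, as real disease signatures are, is median-neutral.
* **Randomized blocks.** Diagnosis is stratified within subtype, and batch
  assignment is diagnosis-stratified within set, mirroring how multiplexed
  designs randomize case/control across plexes. Without this, part of the
  diagnosis effect is statistically indistinguishable from a batch effect
  and no harmonization could preserve it.
* **Biomarkers.** Immunoassay t-tau and p-tau181 are linear in the module-2
  factor, amyloid-beta 42 is negatively linear in the module-1 factor, with
  AD offsets sized so the AD tau/amyloid ratio clears the diagnostic
  confirmation threshold of 0.226. Set 2 biomarker values are scaled by a
  common platform factor, which preserves the ratio and motivates the
  per-set z-scoring step.
* **GIS channels** are the exact per-batch median profile, appended
  noise-free and never given missing cells; they are the normalization
  anchor, not a measured sample.
* **Missingness** is missing-completely-at-random by default; the real
  mechanism in TMT proteomics is partly intensity-dependent, and the tests
  therefore say nothing about informative missingness.
* **Shared ground truth across cohorts.** `protein_seed` draws baselines and
  loadings from a separate stream, so two cohorts generated with the same
  `protein_seed` but different `seed` share planted protein structure while
  drawing independent samples — the setting required by the cross-cohort
  transfer property.

What the generator does *not* emulate: reporter-ion physics,
peptide-to-protein rollup, intensity-dependent missingness, heavy-tailed
abundance distributions, or correlated (non-factor) noise. Passing tests on
this generator demonstrate correctness of the algorithms under their stated
assumptions, not performance on any particular real cohort.

# Harmonization

Proteins observed in at least 50 percent of non-GIS samples are retained
(inclusive comparison). AD-labelled samples whose immunoassay t-tau /
amyloid-beta-42 ratio falls below 0.226 are excluded (the threshold itself
is kept, also inclusive); the cognition-score incongruence rule seen in
practice is exposed as a pluggable predicate because no fixed cut is
defensible, and it defaults to off.

The two-round harmonization expresses each protein as a log2 ratio to its
batch's GIS reference (the median over that batch's GIS channels — median
rather than mean for consistency with the median polish that follows),
median-polishes the protein-by-sample grid within each set, concatenates the
sets, re-anchors each protein to its median over non-Hispanic White control
samples, and polishes again. Protein (row) effects are retained with the
residuals — they are the abundance profile — while sample and overall
effects are discarded as nuisance. GIS columns are dropped from the output
and the missingness pattern is never altered.

The median polish kernel sweeps rows first, then columns, and stops when the
largest absolute adjustment in a sweep falls below `tol` (default `1e-4` on
the log2 scale) or after `maxIter = 20` sweeps, returning a warning and the
partial decomposition when it does not converge; on realistic grids the
residual movement at that point is far below the data's noise floor. Ties in
medians use the standard midpoint rule.

Remaining set/batch variance is removed by bootstrap regression: per
protein, a linear model on nuisance plus preserved factors is fitted on 100
bootstrap resamples of the samples, coefficients are averaged, and only the
nuisance component is subtracted, leaving diagnosis, race, sex and age
effects untouched. Variance fractions are computed by fixed-effect
sequential sums of squares averaged over all factor orderings
(Lindeman-Merenda-Gold), which is order-independent and sums to one; this
fixed-effect decomposition is a deliberate simplification of mixed-model
variance partition and requires a complete matrix, so it is run on
kNN-imputed data. The kNN imputation (neighbour proteins by Euclidean
distance over shared observed samples) is used *only* for variance
partition and per-module PCA; network construction and subtyping always
work on unimputed values with pairwise-complete correlations.

A note on what "preserving" an effect means: when batches are confounded
with a factor, the between-batch component of that factor's effect cannot be
distinguished from a batch effect and is removed by any batch correction.
The generator therefore randomizes diagnosis across batches, and retention
is measured against the realized pre-harmonization effect.

# Co-expression network

The correlation is the biweight midcorrelation (bicor): observations are
weighted by a bisquare function of their distance from the median in units
of 9 median-absolute-deviations, with a Pearson fallback for a variable
whose MAD is zero. The scalar `bicor()` recomputes median and MAD on the
jointly observed subset and is the reference definition; the matrix version
transforms each profile once on its observed entries and renormalizes per
pair, the standard fast treatment for large matrices. Pairs with fewer than
10 jointly observed samples are flagged missing, never zero. Bicor is robust
to outliers but degrades on strongly bimodal vectors, where the majority
mode captures the median and the informative minority mode is down-weighted;
the signed network's inputs (protein profiles across hundreds of samples)
are effectively continuous, so this regime does not arise in the pipeline
itself.

Adjacency is the signed soft-threshold $a = ((1+r)/2)^\beta$ with
$\beta = 6$, and similarity is the topological overlap measure with the
*mean* denominator,
$\mathrm{TOM}_{ij} = (\sum_u a_{iu}a_{uj} + a_{ij}) /
(\mathrm{mean}(k_i,k_j) + 1 - a_{ij})$.
Proteins are clustered by average-linkage hierarchical clustering on
$1-\mathrm{TOM}$ in a single block (a few thousand proteins fit in memory;
block-wise decomposition is an efficiency device, not part of the model).

The dendrogram is cut by a simplified dynamic-hybrid rule with three parts:

1. a static cut at a height fraction mapped from `deep_split` (0-4 maps to
   0.99, 0.97, 0.95, 0.92, 0.90 of the height range; default 2);
2. recursive bisection of each branch while the two halves' eigenproteins
   are dissimilar enough (1 - correlation above the merge height) that the
   merge step would not rejoin them — this recovers distinct modules that a
   single static cut leaves glued together;
3. a cohesion filter dissolving branches whose mean pairwise bicor falls
   below `min_cohesion = 0.3`. The mean pairwise correlation is used rather
   than mean kME because kME to a branch's own eigenprotein is roughly the
   square root of the mean pairwise correlation and therefore flatters
   chance-correlated background branches (a noise branch with mean pairwise
   correlation 0.15 shows mean kME near 0.4). The 0.3 floor was chosen once
   to separate the two regimes the cutter must handle — genuine modules
   (mean pairwise bicor well above 0.5 under the generator's defaults) and
   background branches (below 0.2) — and is exposed as a parameter.

Branches smaller than `min_module_size = 10` are dissolved to
`"unassigned"`. The original dynamic tree cut algorithm has further
heuristics; recovery of planted modules is this package's contract, not
line-by-line equivalence, and `deep_split` is a tuning knob tested by
recovery, not by equivalence.

Module eigenproteins are the first principal component of the
protein-standardized module submatrix, scored per sample, scaled to unit sd,
and sign-aligned to correlate positively with the module mean profile;
missing cells are imputed within the module (kNN, k = 10) before the PCA.
Modules whose eigenproteins are closer than the merge cut height of 0.7
(correlation above 0.3) are merged iteratively until stable, and labels are
renamed M1, M2, ... by decreasing size. kME is the bicor of each protein
with each eigenprotein.

Module-trait correlations drop the Set-2 member of every replicate pair
first, so each participant counts once; binary traits are coded 0/1 (male =
1, AA = 1, AD = 1) and the coding is recorded in the output, since results
are sign-sensitive. P-values are Student-t on $n-2$ degrees of freedom and
are reported raw with a Benjamini-Hochberg column available downstream —
whether to adjust across a module-trait grid is a reader's decision, not the
correlation's.

Cell-type (or any marker set, via GMT) enrichment is the one-tailed
over-representation Fisher exact test against the supplied universe with
Benjamini-Hochberg adjustment across all (module, set) tests. Differential
abundance is per-protein one-way ANOVA with Tukey honestly-significant-
difference pairwise p-values and a flagged Bonferroni-adjusted Welch t-test
fallback where a degenerate cell makes Tukey undefined.

# Sample subtyping

Subtyping features are the top 30 proteins by own-module kME from each
module ("module hubs"; ties break lexicographically by protein id, and a
module smaller than 30 contributes all its members). The sample-sample
network is the signed bicor adjacency over hub features at soft power 13,
with a zero diagonal.

Community detection re-implements the modularity-network approach as seeded
Louvain with constraints:

* the weighted graph is sparsified to a target average degree $k$ by keeping
  each node's $\lceil k/2 \rceil$ strongest edges and symmetrizing by union
  (realized degree is reported);
* Louvain modularity maximization runs on the sparsified graph, with the
  R random seed fixed;
* a deterministic local refinement sweep then revisits nodes in fixed order
  and moves each to the neighbouring community with the largest positive
  modularity gain (Louvain's phase one restarted on the final partition),
  which cleans up boundary assignments the single hierarchical pass gets
  wrong;
* communities larger than the maximum size $j$ are recursively re-split on
  their induced subgraph, raising the resolution when a split refuses;
* communities smaller than the minimum size $i$ — and the rare oversized
  community that refuses to split — are dissolved to `"unassigned"`, so
  emitted cluster sizes always satisfy $[i, j]$.

The grid search evaluates every combination of
$i \in \{10, 15, 20, 25\}$, $j \in \{100, ..., 400\}$ and
$k \in \{25, 50\}$ (56 combinations) and selects by the lexicographic rule
(fraction assigned, then modularity, then replicate consistency). "Selected
based on performance" is not otherwise defined, so the rule is explicit,
logged with all 56 scores, and replaceable.

Replicate (same-case) pairs validate the clustering: the consistency
statistic is the fraction of pairs whose members receive the same
non-unassigned label, a pair with an unassigned member counting as
discordant (the conservative choice). Demographic enrichment of each
subtype against the remaining cohort uses the 2-by-2 chi-squared test
without continuity correction, substituting Fisher's exact test (flagged)
when an expected count drops below 5.

# Cross-cohort transfer

Transfer to an external cohort uses a supervised 2-D embedding with
out-of-sample projection. Rather than a stochastic neighbour embedding, the
map is deterministic and closed-form, which makes projection and the
distance-based unassignment rule exactly reproducible:

* each subtype receives a fixed anchor on a circle of radius 10;
* a sample's coordinate is the softmax-weighted mean of anchors, the weights
  decaying in squared feature-space distance to each subtype centroid, with
  the temperature set from the class-gap statistic so a typical training
  sample's runner-up class gets weight about 1 percent;
* a radial shrinkage factor pulls samples far from every centroid (beyond
  the 99th percentile of training own-class distances) toward the origin, so
  out-of-distribution profiles land far from every cluster;
* a small seeded random projection of the residual provides within-class
  scatter (scaled to sd 0.5);
* training coordinates are additionally pulled toward their own label's
  anchor with weight `target_weight = 0.6`, the supervision step analogous
  to the target weight of supervised neighbour embeddings. Projection of
  unlabelled external samples never uses labels.

External samples are assigned to the nearest subtype centroid (per-label
coordinate means) in embedding space; a sample farther than 3 embedding
units from every centroid is unassigned, as is a sample missing more than
half the model features. Missing features are imputed with training feature
means and the count reported. Nearest *centroid* was chosen over nearest
member for determinism; a nearest-member mode would be a straightforward
extension. The distance threshold of 3 applies in embedding units and is
stored with the model.

Signature comparison across cohorts computes per-protein subtype means,
subtracts the reference subtype's mean, z-scores per protein across the
non-reference subtypes (the z axis is per protein so each protein's profile
is comparable across cohorts; the per-subtype alternative is a one-line
change), drops the reference column, and correlates matched columns with
bicor over the shared proteins (at least 30 required), with Student-t
p-values.

# Spike-in dose-response

The dilution-series generator plants, per protein class, a total log2
change at the top dose, interpolated linearly over the ordered dose index —
the concentrations span three orders of magnitude, so the index (equivalent
to log-concentration spacing) is the natural scale. Percent-of-baseline is
computed on the linear scale (log2 values exponentiated before averaging;
the only scale on which statements like "281 percent of baseline" are
meaningful), so the baseline condition is 100 by construction.

Module-level testing restricted to baseline versus top dose uses
related-measures one-way ANOVA with the protein as the repeated unit
(condition plus protein-block ANOVA; for two conditions this is the paired
t-test) and Tukey adjustment within the condition comparisons, with
Benjamini-Hochberg across modules as a secondary column. Values more than 5
leave-one-out standard deviations from their module mean are excluded from
the statistics but retained for plotting tables — leave-one-out, because a
single extreme value inflates the naive all-points standard deviation
enough to hide itself. Per-module regression pools a module's proteins as
replicates in an ordinary least squares of log2 abundance on dose index,
with a log10-concentration mode behind a flag. An HSA (human serum albumin)
series generated with all-zero slopes serves as the negative control.

# Problem sizes and determinism

The test suite and the acceptance script run the standard cohort (400
samples by 1000 proteins) once and reuse it; simulation-based calibration
checks use 60 to 1000 replicates per test, sizes at which the whole suite
completes in a few minutes on one core. All stochastic steps take explicit
seeds: the generator, the community detection, the embedding and every
simulation loop, so identical inputs give identical outputs across runs and
platforms.

# Known limitations

* The tree cut and the community detection are re-implementations tested by
  planted-structure recovery, not bit-identical ports of the original
  toolboxes.
* The fixed-effect variance partition understates uncertainty relative to a
  mixed model when batches are few and unbalanced.
* Bicor's bisquare weights are unsuitable for strongly bimodal vectors
  (majority mode wins); none of the pipeline's inputs are of that shape, but
  users applying `bicor()` to hand-built two-cluster summaries should
  expect attenuated values.
* The MCAR missingness default means tests do not probe
  intensity-dependent censoring, which real TMT data exhibit.
* The supervised embedding is a deterministic stand-in for stochastic
  neighbour embeddings; its contract is self-consistency, correct transfer
  and distance-based unassignment, not reproduction of any particular
  published layout.
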