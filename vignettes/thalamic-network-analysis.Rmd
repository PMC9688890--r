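---
title: "Intrinsic thalamic structural covariance networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intrinsic thalamic structural covariance networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Thalamic involvement is an early and clinically relevant feature of multiple
sclerosis, and fatigue is among its most disabling symptoms. Beyond the
volumes of the 25 thalamic nuclei per hemisphere that modern segmentation
provides, the *covariance structure* of those volumes across subjects can be
read as a network: nuclei whose volumes rise and fall together across a
group are taken to be structurally connected. `thalnet` implements the full
group-level analysis of such intrinsic thalamic structural covariance
networks, from a tabular cohort of absolute nucleus volumes to binary graphs,
small-world metrics, AUC summaries, and permutation group tests -- together
with the upstream eTIV-normalized volumetry and a synthetic cohort generator
that makes every stage testable without clinical data.

## The pipeline

For each group (F-MS, NF-MS, HC):

1. **Volumetry normalization.** Each absolute volume becomes a percentage of
   the subject's estimated total intracranial volume:
   volume (%) = absolute volume / eTIV x 100. Group volumetry uses one-way
   ANOVA per region with pooled-variance Bonferroni post hoc tests at
   0.05/50 = 0.001.
2. **Residualization.** Every nucleus volume is regressed (OLS, per group)
   on age, sex (0 = female, 1 = male) and lesion volume; residuals replace
   the raw values. Covariates constant within a group (lesion volume in
   controls) are dropped automatically.
3. **Correlation network.** The 50 x 50 matrix `C[i, j]` holds the
   product-moment correlations of the residual columns ("correlation of
   covariate-residualized volumes"). A `full_partial` mode instead derives
   pairwise partial correlations from a shrinkage-regularized precision
   matrix (see *Design choices*).
4. **Binarization.** At each density `d` of the grid 0.05-0.40 (step 0.01,
   36 points), the `k = round(d * 1225)` node pairs with the largest `|C|`
   receive an edge. Rank thresholding guarantees identical edge counts in
   all groups at each density, which AUC comparison requires.
5. **Graph metrics.** Global: clustering coefficient Cp, characteristic path
   length Lp, global efficiency Eglob, local efficiency Eloc, and the
   normalized gamma = Cp/Cp_rand, lambda = Lp/Lp_rand, sigma = gamma/lambda,
   where the null averages run over degree-preserving Maslov--Sneppen
   rewired networks. Nodal: degree, nodal efficiency, betweenness.
6. **AUC summaries.** Each metric's curve over the grid is summarized by its
   composite-trapezoid area under the curve, a threshold-free scalar, and by
   its average value across the grid.
7. **Inference.** Between-group AUC differences are tested by permutation:
   pooled subjects are relabeled into pseudo-groups of the original sizes
   and the *entire* pipeline (residualization included) is re-run on each
   relabeling; `p = (1 + #{|null| >= |obs|}) / (B + 1)`, two-sided. Nodal
   families share one set of relabelings across the 50 nodes and are
   Benjamini--Hochberg corrected at 0.05.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `sparsity_min/max/step` | 0.05 / 0.40 / 0.01 | density grid (fraction of the 1225 possible edges) |
| `n_null_networks` | 200 | rewired nulls behind gamma/lambda/sigma (must exceed 150) |
| `n_null_networks_perm` | 50 | reduced null count inside each permutation |
| `n_permutations` | 5000 | relabelings per permutation test |
| `volumetry_alpha` | 0.001 | per-region ANOVA level (0.05 Bonferroni / 50) |
| `fdr_alpha` | 0.05 | BH level across the 50-node families |
| `covariates` | age, sex, lesion_volume | regressed out before correlation |

All randomness flows from one root seed (`rng_seed`); every stage derives
its own stream via `derive_seed()`, so stage order cannot change results,
and identical configurations replay byte-identically.

## Design choices where the design was open

* **"Partial correlation" with 50 regions and ~25 subjects.** Conditioning
  every pair on the other 48 regions is not estimable at these sample
  sizes without regularization. The default therefore implements the
  correlation of covariate-residualized volumes (equivalent to partialling
  out exactly the regressed covariates), which matches the pipeline's own
  regression step; `full_partial` (linear shrinkage of the correlation
  matrix toward the identity, analytic variance-minimizing intensity,
  partial correlations from the inverse) is available for sensitivity
  analysis. With exactly two regions and zero shrinkage the two modes
  coincide, which the tests verify.
* **Correlation threshold vs sparsity threshold.** The grid is explicitly a
  sparsity grid, so binarization is rank-based with an exact edge count per
  density (round half away from zero; ties at the cutoff broken by the
  fixed lexicographic pair order). Negative correlations enter through the
  absolute value.
* **Disconnected graphs.** At the sparsest densities (61 edges on 50 nodes)
  graphs are usually disconnected. Lp averages the finite distances only
  and reports the unreachable-pair fraction alongside; efficiencies use
  1/Inf = 0; gamma/lambda exclude (and count) nulls with undefined Lp.
* **Betweenness** uses fractional (tie-splitting) shortest-path credit,
  unnormalized, on the unordered-pair convention.
* **Permutation design.** Residualization is re-run inside every
  permutation on the permuted groups, so no group structure can leak
  through the residuals. Relabelings derive from the *sorted* group pair,
  making the p-value invariant to argument order. For gamma/lambda/sigma
  the per-permutation null-network count is reduced to
  `n_null_networks_perm` to bound cost; the observed statistic always uses
  the full `n_null_networks`.
* **Per-group vs pooled residualization.** Whether covariates should be
  regressed out within each group or once across all subjects is genuinely
  open; the default is per group (regression precedes the per-group matrix
  construction), with `pooled_residualization = TRUE` available as a
  sensitivity flag. In pooled mode the residuals are permutation-invariant,
  so permutations reuse the same residual matrix.
* **Post hoc volumetry.** The post hoc is defined as pooled-variance
  two-group t-tests Bonferroni-multiplied by 3 and capped at 1. Degenerate
  regions with no between-group variance report F = 0, p = 1.

## The synthetic cohort generator

The generator emulates the study conditions: group sizes 25/25/40; eTIV
drawn per group (means 1336.7 / 1328.0 / 1396.0 mL, SDs 256-282 mL); nucleus
volumes simulated on the percent-of-eTIV scale around control-group means
and SDs and converted to absolute volumes through each subject's eTIV, so
the normalization stage is exercised nontrivially. Ages are truncated
normals in 18-45 y (group means 33 / 29.5 / 28), sex is ~65% female, lesion
volume is log-normal with median 6.3 mL (patients only, 0 for controls).
Covariate effects are linear per region in units of the region's SD:
-0.015 SD per year of age, -0.20 SD for male sex (larger heads dilute the
percent scale), -0.04 SD per mL of lesion volume -- chosen once as plausible
magnitudes so that residualization has real work to do. The default atrophy
maps shrink the nuclei reported atrophied at the 0.001 level in fatigued
(right AV, bilateral LD, right CL, right LGN, right PuA, bilateral PuM,
bilateral PuI) and non-fatigued (bilateral LD, right PuM, right PuI) MS, by
the reported mean ratios (16-42%).

The covariance model is a block structure over the six anatomical nucleus
groups (anterior, lateral, ventral, intralaminar, medial, posterior; blocks
span hemispheres) with within-block correlation 0.45 and between-block 0.15
-- a plausible, clearly-labeled assumption, not an anatomical claim. The
implied correlation matrix is checked for positive definiteness whenever a
spec is built.

**What the generator does not emulate:** images, lesion geometry,
segmentation error, hemispheric asymmetries of covariance, non-Gaussian
volume distributions, or longitudinal change. Passing tests therefore show
that the *pipeline* behaves correctly and is calibrated under a realistic
correlation structure; they do not validate biological claims about real
cohorts.

### Planted network differences

`plant_network_difference()` alters only the target group's covariance so
that effect recovery can be quantified. The preset replaces the block model
with a ring model with a floor: correlations decay as `rho^ringdistance`
along a fixed ordering of the 50 nuclei but never fall below `floor`, and
the designated node's correlations (default `Right-MDm`) are multiplied by
a decoupling factor. Low-density edges then concentrate on ring neighbours
(lengthening shortest paths), while the designated node is starved of
edges (lowering its nodal efficiency and betweenness). The constants were
fixed by a one-time calibration run and are not revisited:

* `moderate`: rho = 0.80, floor = 0.40, decouple = 0.15
* `strong`: rho = 0.90, floor = 0.50, decouple = 0.02

Under `strong` (n = 25/25), the target group's Lp AUC exceeds the
comparison group's in essentially every replicate, the designated node's
efficiency AUC is lower in essentially every replicate, and the Lp
permutation test at B = 1000 rejects in well over 80% of replicates. The
rejection-rate dial is monotone none < moderate < strong.

A caveat the package states openly: a *single* node's FDR-corrected flag
across a 50-node family is a much harder target than the observed AUC
difference. A BH flag at 0.05 with B = 1000 requires a raw permutation p
near 1/(B+1), i.e. an observed difference beyond essentially every
permutation; at n = 25 per group, the sample-correlation noise
(sd ~ 0.2 per coefficient) interacting with rank thresholding leaves the
per-node permutation null with tails that make this a low-probability
event (roughly 10-25% of replicates under `strong`) regardless of how
completely the node is decoupled. The designated node's *observed*
efficiency deficit is nevertheless essentially always present and its raw
p concentrates near the smallest attainable values.

## Numerical choices

* Edge counts per density: `round(d * N(N-1)/2)`, half away from zero
  (0.05 -> 61 edges, 0.40 -> 490 on 50 nodes).
* AUC: composite trapezoid over the stored grid points; undefined points
  are dropped with their densities and logged.
* Distances: breadth-first search over 64-bit node-set masks (the compiled
  core supports up to 64 nodes); betweenness via Brandes' algorithm.
* Rewiring: attempted double-edge swaps, 10 x edge count by default,
  rejecting self-loops and multi-edges; degree sequences are preserved
  exactly, and a graph admitting no legal swap is returned with a warning.
* Tiny simulated percent volumes are floored at 2% of the region's base
  mean so generated cohorts always pass the positivity validation.

## Problem sizes used by the shipped tests and scripts

The test suite calibrates type I error on 500 replicate cohorts (B = 200)
and quantifies planted-effect recovery on 100 replicates (B = 1000); the
brute-force oracle comparisons run 200 random graphs with up to 8 nodes;
the volumetry null calibration simulates 10,000 regions. The analysis
scripts and `scripts/acceptance.R` run the full pipeline at B = 1000
permutations with 200 observed-network nulls. These sizes are the package's
choices for routine runs; `run_config()` accepts the full B = 5000 of the
original design.

## Known limitations

* Group-level networks only: one network per group, so no per-subject
  network metrics and no correlation of network metrics with clinical
  scores.
* Binary, undirected graphs only; no weighted variants, rich-club,
  modularity or hub taxonomy.
* The compiled graph core is limited to 64 nodes -- ample for the 50-nucleus
  parcellation it serves.
* The exact post hoc variant behind published volumetry tables is often
  unstated; the pooled-variance Bonferroni defined here is one standard
  choice and is not claimed to reproduce any particular published table.
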