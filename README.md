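# thalnet

Group-level analysis of the **intrinsic thalamic structural covariance
network** in multiple sclerosis cohorts: from a per-subject table of the 50
thalamic nucleus volumes (25 per hemisphere, FreeSurfer
`segmentThalamicNuclei` scheme) and covariates to binary graphs over a
sparsity grid, small-world and nodal metrics, AUC summaries, permutation
group tests with FDR control, and eTIV-normalized group volumetry. It is
written for neuroimaging groups studying thalamic involvement in
MS-related fatigue (fatigued patients F-MS, non-fatigued NF-MS, healthy
controls HC), but any three-group tabular volumetry fits the schema.

## The method

Per group, nucleus volumes are residualized against age, sex and lesion
load (OLS, per region), and the inter-regional matrix *C<sub>ij</sub>*
(i, j = 1..N, N = 50) holds the correlations of those residuals across
subjects. *C* is thresholded into binary matrices *A<sub>ij</sub>* at every
density of the sparsity grid 0.05–0.40 (step 0.01, 36 points): the
`round(d·N(N−1)/2)` pairs with the largest |C<sub>ij</sub>| receive an
edge. On each graph the package computes the clustering coefficient
*C<sub>p</sub>*, characteristic path length *L<sub>p</sub>* (finite pairs
only, unreachable fraction reported), global and local efficiency
*E<sub>glob</sub>*, *E<sub>loc</sub>*, and the normalized
γ = C<sub>p</sub>/C<sub>p</sub><sup>rand</sup>,
λ = L<sub>p</sub>/L<sub>p</sub><sup>rand</sup>, σ = γ/λ, where the null
means come from degree-preserving (Maslov–Sneppen) rewired networks;
nodally, degree, nodal efficiency and betweenness centrality. Each metric's
curve over the grid is summarized by its trapezoid AUC, and between-group
AUC differences are tested by permutation (the full pipeline re-run on each
relabeling), two-sided with the add-one rule; the 50-node families are
Benjamini–Hochberg corrected at 0.05. Volumetry uses
volume (%) = absolute volume / eTIV × 100 with one-way ANOVA and
pooled-variance Bonferroni post hoc tests at 0.05/50 = 0.001.

Because clinical cohorts of this kind are typically not shareable, the
package includes a synthetic cohort generator (`synthetic_cohort_spec()`,
`generate_cohort()`) reproducing the study conditions — group sizes
25/25/40, realistic nucleus means/SDs on the percent-of-eTIV scale,
per-group eTIV distributions, covariate effects, block covariance over the
six anatomical nucleus groups — plus `plant_network_difference()`, which
installs calibrated longer-path/starved-node effects for power evaluation.
See the methods vignette (`vignettes/thalamic-network-analysis.Rmd`) for
the model, parameter and design details.

## Worked example

```r
library(thalnet)

spec   <- plant_network_difference(synthetic_cohort_spec(), "F-MS", "strong")
cohort <- generate_cohort(spec, seed = 20221113)
cfg    <- run_config(n_permutations = 1000, rng_seed = 20221113)

pr <- permutation_group_difference(cohort, c("F-MS", "NF-MS"), "Lp", cfg)
```

The analysis drivers under `analysis/` run the full sequence
(`01_simulate_cohort.R` → `02_volumetry.R` → `03_global_network.R` →
`04_nodal_network.R`) and write their tables under `results/`. Step 3
prints, for this seed:

```
Small-world regime (average sigma over the grid):
 group  average       auc
  F-MS 2.395519 0.8317828
 NF-MS 1.319168 0.4555855
    HC 1.467165 0.5130322

Permutation tests on metric AUCs:
  F-MS vs HC Lp          avg  2.6969 vs  2.1830  dAUC  +0.1542  p = 0.001 *
  ...
  F-MS vs NF-MS Lp       avg  2.6969 vs  2.0702  dAUC  +0.1937  p = 0.001 *
  F-MS vs NF-MS Eglob    avg  0.5072 vs  0.4265  dAUC  +0.0288  p = 0.025 *
  F-MS vs NF-MS Cp       avg  0.5644 vs  0.5080  dAUC  +0.0206  p = 0.140
```

Every group is small-world (σ > 1 across the whole grid), and the planted
effect is recovered: the fatigued group's characteristic path length is
markedly higher (average 2.70 vs 2.07 hops; AUC difference +0.19,
permutation p ≈ 0.001), i.e. poorer global integration of the intrinsic
thalamic network. Step 2 reports the count of nuclei flagged as atrophied
at the 0.001 level in each patient group, and step 4 the per-node AUC
tests after FDR.

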