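#!/usr/bin/env Rscript

# Step 2: volumetry.
#
# Normalizes every nucleus volume to percent of eTIV, compares the three
# groups region by region (one-way ANOVA with pooled-variance Bonferroni
# post hoc, alpha = 0.05/50 = 0.001), and correlates nucleus volumes with
# lesion load, disease duration and age in the patients (Spearman).

suppressPackageStartupMessages(library(thalnet))

cohort <- read_cohort_table("results/cohort.csv")
norm <- normalize_volumes(cohort)

vs <- volumetry_stats(norm, alpha = 0.001, include_whole = TRUE)

clin <- do.call(rbind, lapply(thalamic_nucleus_labels(), function(region) {
  do.call(rbind, lapply(c("lesion_volume", "disease_duration", "age"),
                        function(v) correlate_clinical(norm, region, v)))
}))

write_results(list(volumetry = vs, clinical_correlations = clin), "results")

cat("Volumetry table: results/volumetry.tsv\n")
cat(sprintf("nuclei atrophied in F-MS vs HC (p < 0.001): %d\n",
            sum(vs$sig_FMS_vs_HC & vs$mean_FMS < vs$mean_HC)))
cat(sprintf("nuclei atrophied in NF-MS vs HC (p < 0.001): %d\n",
            sum(vs$sig_NFMS_vs_HC & vs$mean_NFMS < vs$mean_HC)))
cat(sprintf("nuclei different between F-MS and NF-MS: %d\n",
            sum(vs$sig_FMS_vs_NFMS)))
strong <- clin[clin$variable == "lesion_volume" & clin$p < 0.001, ]
cat("nuclei correlated with lesion volume (p < 0.001):",
    nrow(strong), "\n")
if (nrow(strong) > 0) {
  print(strong[order(strong$rho), c("region", "rho", "p")], row.names = FALSE)
}
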