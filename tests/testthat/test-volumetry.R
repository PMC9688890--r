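test_that("volume normalization implements percent-of-eTIV exactly", {
  df <- tiny_cohort_df()
  df$eTIV <- c(1000, 1000, 1000)
  df[["Left-AV"]] <- c(5, 5, 5)
  co <- as_cohort_table(df)
  norm <- normalize_volumes(co)
  expect_equal(norm[["Left-AV"]], c(0.5, 0.5, 0.5))

  # absolute = eTIV gives 100%
  df2 <- tiny_cohort_df()
  df2[["Right-PuM"]] <- df2$eTIV
  n2 <- normalize_volumes(as_cohort_table(df2))
  expect_equal(n2[["Right-PuM"]], c(100, 100, 100))

  # scale invariance: doubling volume and eTIV leaves percents unchanged
  df3 <- tiny_cohort_df()
  co3 <- as_cohort_table(df3)
  df4 <- df3
  labs <- thalamic_nucleus_labels()
  df4[labs] <- df4[labs] * 2
  df4$eTIV <- df4$eTIV * 2
  expect_equal(normalize_volumes(as_cohort_table(df4))[labs],
               normalize_volumes(co3)[labs])

  # linear in absolute volume, inverse-linear in eTIV (random scalings)
  set.seed(4)
  a <- runif(1, 0.5, 3)
  df5 <- df3
  df5[labs] <- df5[labs] * a
  expect_equal(as.matrix(normalize_volumes(as_cohort_table(df5))[labs]),
               a * as.matrix(normalize_volumes(co3)[labs]))
})

test_that("derived whole-thalamus percents equal the sum of nucleus percents", {
  norm <- normalize_volumes(small_cohort(seed = 2))
  norm <- add_whole_thalamus(norm)
  labs <- thalamic_nucleus_labels()
  expect_equal(norm$Whole, rowSums(norm[labs]))
  expect_equal(norm$`Left-Whole` + norm$`Right-Whole`, norm$Whole)
})

test_that("ANOVA F and post hoc p-values match the sums-of-squares oracle", {
  norm <- normalize_volumes(small_cohort(seed = 3))
  for (region in c("Left-AV", "Right-MDm", "Right-PuI")) {
    row <- anova_posthoc(norm, region)
    expect_equal(row$F, oracle_anova_f(norm[[region]], norm$group),
                 tolerance = 1e-10)
    expect_true(all(c(row$p_FMS_vs_HC, row$p_NFMS_vs_HC,
                      row$p_FMS_vs_NFMS) >= 0))
    expect_true(all(c(row$p_FMS_vs_HC, row$p_NFMS_vs_HC,
                      row$p_FMS_vs_NFMS) <= 1))
  }
  # fabricated data with hand-computed sums of squares
  df <- tiny_cohort_df()
  df <- df[rep(1:3, each = 3), ]
  df$subject_id <- paste0("s", 1:9)
  df[["Left-AV"]] <- c(1, 2, 3, 2, 3, 4, 6, 7, 8)
  norm2 <- df
  class(norm2) <- c("normalized_volumes", "data.frame")
  row <- anova_posthoc(norm2, "Left-AV")
  # groups (1,2,3),(2,3,4),(6,7,8): SSB = 3*((2-4)^2+(3-4)^2+(7-4)^2) = 42
  # SSW = 6; F = (42/2)/(6/6) = 21
  expect_equal(row$F, 21, tolerance = 1e-12)
})

test_that("degenerate ANOVA inputs are handled explicitly", {
  df <- tiny_cohort_df()
  df <- df[rep(1:3, each = 2), ]
  df$subject_id <- paste0("s", 1:6)
  df[["Left-AV"]] <- rep(5, 6) # identical everywhere: F = 0, p = 1
  norm <- df
  class(norm) <- c("normalized_volumes", "data.frame")
  row <- anova_posthoc(norm, "Left-AV")
  expect_equal(row$F, 0)
  expect_equal(row$p_anova, 1)
  expect_false(row$sig_FMS_vs_HC)

  # fewer than 3 groups errors
  norm2 <- norm[norm$group != "HC", ]
  expect_error(anova_posthoc(norm2, "Left-AV"), "three groups")
})

test_that("volumetry_stats produces one calibrated row per region", {
  norm <- normalize_volumes(small_cohort(seed = 7))
  vs <- volumetry_stats(norm, alpha = 0.001, include_whole = TRUE)
  expect_equal(nrow(vs), 53)
  expect_true(all(vs$p_anova >= 0 & vs$p_anova <= 1))
  expect_identical(vs$sig_FMS_vs_HC, vs$p_FMS_vs_HC < 0.001)
})

test_that("clinical correlations match a rank-based oracle and handle edge cases", {
  norm <- normalize_volumes(small_cohort(seed = 11))
  # perfect monotone association
  norm2 <- norm
  norm2[["Left-AV"]] <- norm2$lesion_volume + 1
  r <- correlate_clinical(norm2, "Left-AV", "lesion_volume")
  expect_equal(r$rho, 1)
  norm2[["Left-AV"]] <- max(norm2$lesion_volume) + 1 - norm2$lesion_volume
  r <- correlate_clinical(norm2, "Left-AV", "lesion_volume")
  expect_equal(r$rho, -1)

  # random paired data against the brute-force rank-correlation oracle
  set.seed(12)
  for (i in 1:5) {
    region <- sample(thalamic_nucleus_labels(), 1)
    r <- correlate_clinical(norm, region, "lesion_volume", "spearman")
    pats <- norm[norm$group != "HC", ]
    expect_equal(r$rho, oracle_spearman(pats$lesion_volume, pats[[region]]),
                 tolerance = 1e-12)
    expect_equal(r$n, nrow(pats))
  }
  # Pearson path agrees with stats::cor
  r <- correlate_clinical(norm, "Right-PuI", "age", "pearson")
  pats <- norm[norm$group != "HC", ]
  expect_equal(r$rho, cor(pats$age, pats[["Right-PuI"]]), tolerance = 1e-12)

  # zero-variance input is an explicit error
  norm3 <- norm
  norm3[["Left-AV"]] <- 1
  expect_error(correlate_clinical(norm3, "Left-AV", "age"), "zero variance")
})
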