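test_that("generated cohorts are reproducible and pass validation", {
  spec <- synthetic_cohort_spec()
  a <- generate_cohort(spec, seed = 7)
  b <- generate_cohort(spec, seed = 7)
  expect_identical(a, b)
  expect_s3_class(a, "cohort_table") # construction runs full validation
  expect_equal(as.vector(table(a$group)[c("F-MS", "NF-MS", "HC")]),
               c(25L, 25L, 40L))
  expect_true(all(a$lesion_volume[a$group == "HC"] == 0))
  expect_true(all(is.na(a$disease_duration[a$group == "HC"])))
  expect_true(all(a$lesion_volume[a$group != "HC"] > 0))
  expect_true(all(a$age >= 18 & a$age <= 45))
  c_ <- generate_cohort(spec, seed = 8)
  expect_false(identical(a$eTIV, c_$eTIV))
})

test_that("group means and block correlations match the spec at large n", {
  spec <- synthetic_cohort_spec(
    n_fms = 5000, n_nfms = 100, n_hc = 100,
    atrophy = list(`F-MS` = numeric(0), `NF-MS` = numeric(0), HC = numeric(0)),
    beta_age = 0, beta_sex_male = 0, beta_lesion = 0)
  co <- generate_cohort(spec, seed = 9)
  norm <- normalize_volumes(co)
  f <- norm[norm$group == "F-MS", ]
  # with no atrophy and no covariate effects, percent means approach the
  # base means (sampling check)
  mns <- colMeans(f[thalamic_nucleus_labels()])
  expect_true(all(abs(mns - spec$base_mean) < 5 * spec$base_sd / sqrt(5000)
                  + 1e-6))
  # same-block pair correlates near r_in, cross-block near r_out
  r_same <- cor(f[["Left-VA"]], f[["Right-VLp"]]) # both ventral
  r_cross <- cor(f[["Left-VA"]], f[["Right-PuM"]])
  expect_lt(abs(r_same - spec$r_in), 0.05)
  expect_lt(abs(r_cross - spec$r_out), 0.05)
})

test_that("atrophy maps shift only the targeted regions", {
  spec <- synthetic_cohort_spec(
    n_fms = 4000, n_nfms = 100, n_hc = 4000,
    atrophy = list(`F-MS` = c("Right-PuI" = 0.3), `NF-MS` = numeric(0),
                   HC = numeric(0)),
    beta_age = 0, beta_sex_male = 0, beta_lesion = 0)
  norm <- normalize_volumes(generate_cohort(spec, seed = 10))
  f <- colMeans(norm[norm$group == "F-MS", thalamic_nucleus_labels()])
  h <- colMeans(norm[norm$group == "HC", thalamic_nucleus_labels()])
  expect_equal(unname(f[["Right-PuI"]] / h[["Right-PuI"]]), 0.7,
               tolerance = 0.03)
  others <- setdiff(thalamic_nucleus_labels(), "Right-PuI")
  expect_true(all(abs(f[others] / h[others] - 1) < 0.05))
})

test_that("covariate effects are recoverable by regression", {
  spec <- synthetic_cohort_spec(n_fms = 3000, n_nfms = 100, n_hc = 100,
                                atrophy = list(`F-MS` = numeric(0),
                                               `NF-MS` = numeric(0),
                                               HC = numeric(0)))
  norm <- normalize_volumes(generate_cohort(spec, seed = 11))
  f <- norm[norm$group == "F-MS", ]
  fit <- lm(f[["Left-VPL"]] ~ f$age + I(f$sex == "male") + f$lesion_volume)
  sd_r <- spec$base_sd[["Left-VPL"]]
  expect_lt(abs(unname(coef(fit)[2]) - spec$beta_age * sd_r), 2e-4)
  expect_lt(abs(unname(coef(fit)[3]) - spec$beta_sex_male * sd_r), 2.5e-3)
})

test_that("invalid specs are rejected", {
  expect_error(synthetic_cohort_spec(n_fms = 2), "n_fms")
  expect_error(synthetic_cohort_spec(r_in = 0.2, r_out = 0.4), "r_in")
  # a non-positive-definite override is caught at planting time
  spec <- synthetic_cohort_spec()
  spec$correlation_override[["F-MS"]] <- list(type = "bogus")
  expect_error(generate_cohort(spec, seed = 1), "unknown correlation model")
})

test_that("network presets are the identity for 'none' and plant the effect", {
  spec <- synthetic_cohort_spec()
  expect_identical(plant_network_difference(spec, "F-MS", "none"), spec)
  sp <- plant_network_difference(spec, "F-MS", "strong")
  expect_false(is.null(sp$correlation_override[["F-MS"]]))
  expect_error(plant_network_difference(spec, "F-MS", "extreme"))

  # the strong preset lengthens the target group's Lp AUC and starves the
  # designated node relative to the untouched comparison group
  cfg <- run_config()
  grid <- density_grid(cfg)
  w <- thalnet:::.trapz_weights(grid)
  res <- t(sapply(1:5, function(r) {
    co <- generate_cohort(sp, seed = 300 + r)
    df <- as.data.frame(co)
    out <- sapply(c("F-MS", "NF-MS"), function(g) {
      pc <- thalnet:::.pipeline_curves(df[df$group == g, ], cfg, grid,
                                       want = "Lp", nodal = TRUE)
      c(lp = suppressMessages(auc_trapezoid(grid, pc$global[, "Lp"])),
        ne = as.numeric(pc$nodal_efficiency["Right-MDm", ] %*% w))
    })
    c(dlp = out["lp", 1] - out["lp", 2], dne = out["ne", 1] - out["ne", 2])
  }))
  expect_true(all(res[, "dlp"] > 0))
  expect_true(all(res[, "dne"] < 0))
})
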