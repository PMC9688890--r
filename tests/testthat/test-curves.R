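test_that("trapezoid AUC reproduces closed forms and the refinement oracle", {
  grid <- density_grid(run_config())
  expect_equal(auc_trapezoid(grid, rep(3, 36)), 0.35 * 3, tolerance = 1e-12)
  expect_equal(auc_trapezoid(grid, grid), (0.05 + 0.40) / 2 * 0.35,
               tolerance = 1e-12)
  expect_equal(auc_trapezoid(c(0.05, 0.40), c(1, 1)), 0.35)
  expect_equal(auc_trapezoid(c(0, 1), c(0, 1)), 0.5)
  set.seed(101)
  for (i in 1:20) {
    y <- rnorm(36)
    expect_equal(auc_trapezoid(grid, y), oracle_trapezoid(grid, y),
                 tolerance = 1e-12)
    # refinement of the stored polyline leaves the integral unchanged
    fine_x <- seq(0.05, 0.40, length.out = 3501)
    fine_y <- approx(grid, y, xout = fine_x)$y
    expect_equal(auc_trapezoid(grid, y), oracle_trapezoid(fine_x, fine_y),
                 tolerance = 1e-10)
  }
  # undefined grid points are excluded with their density
  y <- rep(2, 36)
  y[5] <- NA
  expect_message(a <- auc_trapezoid(grid, y), "excluding 1")
  expect_equal(a, oracle_trapezoid(grid[-5], rep(2, 35)), tolerance = 1e-12)
  expect_error(suppressMessages(auc_trapezoid(c(0.05, 0.1), c(NA, 1))),
               "2 usable")
})

test_that("metric curves carry average and AUC consistent with stored points", {
  co <- small_cohort(seed = 102)
  curve <- suppressMessages(metric_curve(co, "HC", "Eglob"))
  expect_length(curve$values, 36)
  expect_equal(curve$average, mean(curve$values))
  expect_equal(curve$auc, curve_auc(curve), tolerance = 1e-12)
  expect_true(all(curve$values >= 0 & curve$values <= 1))
  df <- as.data.frame(curve)
  expect_equal(names(df), c("metric", "group", "density", "value"))

  gm <- suppressMessages(group_metric_curves(
    co, run_config(n_null_networks = 151), metrics = c("Cp", "Lp")))
  expect_equal(nrow(gm$summary), 6)
  expect_equal(nrow(gm$curves), 6 * 36)
})

test_that("permutation p-values are valid, deterministic and symmetric", {
  co <- small_cohort(seed = 103, n = c(8, 8, 8))
  cfg <- run_config(n_permutations = 99, rng_seed = 11)
  pr <- suppressMessages(
    permutation_group_difference(co, c("F-MS", "NF-MS"), "Lp", cfg))
  expect_true(pr$p > 0 && pr$p <= 1)
  expect_equal(pr$observed_diff_auc, pr$auc[[1]] - pr$auc[[2]])
  pr2 <- suppressMessages(
    permutation_group_difference(co, c("F-MS", "NF-MS"), "Lp", cfg))
  expect_identical(pr$p, pr2$p)
  # swapping group order negates the difference, p unchanged
  pr3 <- suppressMessages(
    permutation_group_difference(co, c("NF-MS", "F-MS"), "Lp", cfg))
  expect_equal(pr3$observed_diff_auc, -pr$observed_diff_auc)
  expect_identical(pr3$p, pr$p)
})

test_that("self-vs-self comparison gives zero difference and p = 1", {
  co <- small_cohort(seed = 104, n = c(8, 8, 8))
  df <- as.data.frame(co)
  a <- df[df$group == "F-MS", ]
  b <- a
  b$group <- "NF-MS"
  b$subject_id <- paste0(b$subject_id, "b")
  dup <- as_cohort_table(rbind(a, b))
  cfg <- run_config(n_permutations = 49, rng_seed = 3)
  pr <- suppressMessages(
    permutation_group_difference(dup, c("F-MS", "NF-MS"), "Cp", cfg))
  expect_equal(pr$observed_diff_auc, 0)
  expect_equal(pr$p, 1)
})

test_that("nodal family tests share permutations and respect FDR flags", {
  co <- small_cohort(seed = 105, n = c(8, 8, 8))
  cfg <- run_config(n_permutations = 49, rng_seed = 7)
  nf <- suppressMessages(
    nodal_family_test(co, c("F-MS", "NF-MS"), "nodal_efficiency", cfg))
  expect_equal(nrow(nf), 50)
  expect_identical(nf$node, thalamic_nucleus_labels())
  expect_true(all(nf$p > 0 & nf$p <= 1))
  expect_equal(nf$p_fdr, bh_fdr(nf$p))
  expect_identical(nf$sig, nf$p_fdr < cfg$fdr_alpha)
  expect_equal(nf$diff_auc, nf$auc_A - nf$auc_B)
})

test_that("BH adjustment matches the step-up oracle and its fixed points", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(rep(1, 10)), rep(1, 10))
  # all raw p equal is a BH fixed point
  expect_equal(bh_fdr(rep(0.02, 50)), rep(0.02, 50))
  # hand-expanded step-up case
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(106)
  for (i in 1:20) {
    p <- runif(sample(3:60, 1))
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-15)
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_fdr(c(0.5, -0.1)), "\\[0, 1\\]")
})

test_that("AUC bounds follow from the curve's range", {
  set.seed(107)
  grid <- density_grid(run_config())
  for (i in 1:10) {
    y <- runif(36, -2, 5)
    a <- auc_trapezoid(grid, y)
    expect_lte(a, 0.35 * max(y) + 1e-12)
    expect_gte(a, 0.35 * min(y) - 1e-12)
  }
})

test_that("pooled residualization is honored and deterministic", {
  co <- small_cohort(seed = 108, n = c(8, 8, 8))
  cfg_pool <- run_config(n_permutations = 19, rng_seed = 5,
                         pooled_residualization = TRUE)
  cfg_grp <- run_config(n_permutations = 19, rng_seed = 5)
  a <- suppressMessages(metric_curve(co, "HC", "Cp", cfg_pool))
  b <- suppressMessages(metric_curve(co, "HC", "Cp", cfg_pool))
  expect_identical(a$values, b$values)
  d <- suppressMessages(metric_curve(co, "HC", "Cp", cfg_grp))
  expect_false(identical(a$values, d$values))
  pr <- suppressMessages(
    permutation_group_difference(co, c("F-MS", "NF-MS"), "Lp", cfg_pool))
  expect_true(pr$p > 0 && pr$p <= 1)
})
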