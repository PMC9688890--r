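test_that("residualization matches the normal-equations oracle and is orthogonal", {
  co <- small_cohort(seed = 21, n = c(10, 10, 12))
  res <- residualize(co, "F-MS")
  df <- as.data.frame(co)
  df <- df[df$group == "F-MS", ]
  X <- cbind(1, df$age, as.numeric(df$sex == "male"), df$lesion_volume)
  Y <- as.matrix(df[thalamic_nucleus_labels()])
  expect_equal(unname(res$residuals), unname(oracle_ols_residuals(X, Y)),
               tolerance = 1e-8)
  # columns are centered and orthogonal to every retained covariate
  expect_true(all(abs(colMeans(res$residuals)) < 1e-8))
  for (k in 2:4) {
    expect_true(all(abs(crossprod(X[, k] - mean(X[, k]), res$residuals)) < 1e-6))
  }
})

test_that("constant covariates are dropped and empty covariates mean-center", {
  co <- small_cohort(seed = 22)
  expect_message(res <- residualize(co, "HC"), "lesion_volume")
  expect_false("lesion_volume" %in% res$covariates_used)

  res0 <- residualize(co, "NF-MS", covariates = character(0))
  df <- as.data.frame(co)
  Y <- as.matrix(df[df$group == "NF-MS", thalamic_nucleus_labels()])
  expect_equal(unname(res0$residuals), unname(sweep(Y, 2, colMeans(Y))),
               tolerance = 1e-10)
})

test_that("volumes exactly linear in a covariate leave zero residuals", {
  co <- small_cohort(seed = 23)
  df <- as.data.frame(co)
  df[df$group == "HC", "Left-AV"] <- 0.001 * df$age[df$group == "HC"] + 2
  co2 <- as_cohort_table(df)
  res <- suppressMessages(residualize(co2, "HC"))
  expect_true(all(abs(res$residuals[, "Left-AV"]) < 1e-8))
})

test_that("residual correlation matrix is a valid symmetric network", {
  co <- small_cohort(seed = 24, n = c(12, 12, 14))
  net <- build_correlation_matrix(residualize(co, "F-MS"))
  expect_equal(net$matrix, t(net$matrix))
  expect_true(all(diag(net$matrix) == 0))
  expect_true(all(abs(net$matrix) <= 1 + 1e-12))
  # identical columns correlate at 1
  res <- residualize(co, "F-MS")
  res$residuals[, 2] <- res$residuals[, 1]
  net2 <- build_correlation_matrix(res)
  expect_equal(net2$matrix[1, 2], 1)
  # 5-subject, 3-region toy case against the hand-expanded formula
  R <- matrix(c(1.2, -0.5, 0.3, 0.9, -1.9,
                0.4, 0.8, -1.1, 0.2, -0.3,
                2.0, -1.0, 0.5, 0.1, -1.6), 5, 3)
  colnames(R) <- c("a", "b", "c")
  toy <- structure(list(residuals = R, group = "toy"),
                   class = "residual_table")
  net3 <- build_correlation_matrix(toy)
  byhand <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  expect_equal(net3$matrix[1, 2], byhand(R[, 1], R[, 2]), tolerance = 1e-12)
  expect_equal(net3$matrix[2, 3], byhand(R[, 2], R[, 3]), tolerance = 1e-12)
})

test_that("independent columns decorrelate as n grows", {
  set.seed(31)
  R <- matrix(rnorm(10000 * 6), 10000, 6)
  colnames(R) <- letters[1:6]
  net <- build_correlation_matrix(
    structure(list(residuals = R, group = "x"), class = "residual_table"))
  off <- net$matrix[upper.tri(net$matrix)]
  expect_true(max(abs(off)) < 0.05)
})

test_that("partial-correlation mode equals residual mode for two regions", {
  set.seed(32)
  R <- matrix(rnorm(40), 20, 2)
  colnames(R) <- c("a", "b")
  rt <- structure(list(residuals = R, group = "x"), class = "residual_table")
  p0 <- build_correlation_matrix(rt, mode = "full_partial", shrinkage = 0)
  p1 <- build_correlation_matrix(rt, mode = "residual_pearson")
  expect_equal(p0$matrix, p1$matrix, tolerance = 1e-12)
  # with 50 regions and few subjects the shrunk precision still exists
  co <- small_cohort(seed = 33)
  netp <- build_correlation_matrix(residualize(co, "HC", character(0)),
                                   mode = "full_partial")
  expect_true(all(is.finite(netp$matrix)))
  expect_equal(netp$matrix, t(netp$matrix), tolerance = 1e-12)
})

test_that("zero-variance regions raise an error naming the region", {
  R <- matrix(rnorm(30), 10, 3)
  R[, 2] <- 0
  colnames(R) <- c("a", "b", "c")
  rt <- structure(list(residuals = R, group = "x"), class = "residual_table")
  expect_error(build_correlation_matrix(rt), "b")
})

test_that("the default sparsity grid has 36 inclusive values", {
  grid <- density_grid(run_config())
  expect_length(grid, 36)
  expect_equal(grid[1], 0.05)
  expect_equal(grid[36], 0.40)
  expect_equal(diff(grid), rep(0.01, 35))
  # single-value grid when min = max is rejected by config validation,
  # but a step not dividing the range truncates below the max
  cfg <- run_config(sparsity_min = 0.05, sparsity_max = 0.4,
                    sparsity_step = 0.15)
  expect_message(g2 <- density_grid(cfg), "truncated")
  expect_equal(g2, c(0.05, 0.20, 0.35))
})

test_that("rank binarization yields exact edge counts and nested edge sets", {
  co <- small_cohort(seed = 41, n = c(12, 12, 14))
  net <- build_correlation_matrix(residualize(co, "HC"))
  a40 <- binarize_at_density(net, 0.40)
  expect_equal(a40$n_edges, 490)
  expect_equal(sum(a40$matrix) / 2, 490)
  a05 <- binarize_at_density(net, 0.05)
  expect_equal(a05$n_edges, 61)
  expect_equal(a40$matrix, t(a40$matrix))
  expect_true(all(diag(a40$matrix) == 0))

  # nesting across the whole default grid
  prev <- NULL
  for (d in density_grid(run_config())) {
    A <- binarize_at_density(net, d)$matrix
    if (!is.null(prev)) expect_true(all(A[prev == 1] == 1))
    prev <- A
  }

  # top-k pairs equal an exhaustive sort when all |C| are distinct
  C <- net$matrix
  ut <- which(upper.tri(C))
  expect_true(anyDuplicated(abs(C[ut])) == 0)
  k <- 61
  top <- ut[order(-abs(C[ut]))[seq_len(k)]]
  A <- binarize_at_density(net, 0.05)$matrix
  expect_equal(sort(which(upper.tri(A) & A == 1)), sort(top))

  # binarization only sees the rank order of |C|
  net2 <- net
  net2$matrix <- sign(net$matrix) * abs(net$matrix)^3 # strictly monotone in |C|
  expect_equal(binarize_at_density(net2, 0.17)$matrix,
               binarize_at_density(net, 0.17)$matrix)

  expect_error(binarize_at_density(net, 0.0001), "empty graph")
})
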