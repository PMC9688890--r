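.global_metric_names <- c("Cp", "Lp", "Eglob", "Eloc", "gamma", "lambda",
                          "sigma")
.nodal_metric_names <- c("degree", "nodal_efficiency", "betweenness")

#' Trapezoid area under a metric curve
#'
#' Composite trapezoid rule over the stored (density, value) points. Grid
#' points whose value is undefined (`NA`, e.g. an undefined Lp at a density)
#' are excluded together with their density, with a message.
#'
#' @param densities grid densities.
#' @param values metric values, same length.
#' @return Scalar AUC.
#' @export
auc_trapezoid <- function(densities, values) {
  stopifnot(length(densities) == length(values))
  keep <- !is.na(values)
  if (any(!keep)) {
    message("excluding ", sum(!keep), " undefined grid point(s) from AUC")
  }
  x <- densities[keep]
  y <- values[keep]
  if (length(x) < 2) stop("need at least 2 usable grid points for an AUC")
  sum(0.5 * (y[-1] + y[-length(y)]) * diff(x))
}

# trapezoid weight vector for a fixed grid (vectorized AUCs over nodes)
.trapz_weights <- function(x) {
  dx <- diff(x)
  c(dx / 2, 0) + c(0, dx / 2)
}

# numeric covariate matrix (sex encoded 0 = female / 1 = male); constant
# columns are dropped later, per (pseudo-)group
.cov_matrix <- function(df, covariates) {
  if (length(covariates) == 0) {
    return(matrix(0, nrow(df), 0))
  }
  cols <- lapply(covariates, function(cv) {
    if (!cv %in% names(df)) stop("no such covariate column: ", cv)
    x <- df[[cv]]
    if (cv == "sex") x <- as.numeric(x == "male")
    x <- as.numeric(x)
    if (anyNA(x)) stop("missing values in covariate ", cv)
    x
  })
  m <- do.call(cbind, cols)
  colnames(m) <- covariates
  m
}

# Full network pipeline for one subject set held as matrices:
# residualize -> correlate -> rank-threshold across the grid -> metrics.
# Returns global metric matrix (densities x metrics) and requested nodal
# matrices (nodes x densities).
.matrix_curves <- function(Y, Craw, config, grid,
                           want = c("Cp", "Lp", "Eglob", "Eloc"),
                           nodal = FALSE, betweenness = FALSE,
                           n_null = 0L, null_seed = NULL, resid = NULL) {
  R <- if (is.null(resid)) .residual_matrix(Y, Craw) else resid
  sds <- sqrt(colSums(R^2))
  if (any(sds == 0)) {
    stop("zero-variance residuals for region(s): ",
         paste(colnames(Y)[sds == 0], collapse = ", "))
  }
  C <- if (config$correlation_mode == "full_partial") {
    build_correlation_matrix(
      structure(list(residuals = R, group = "tmp"), class = "residual_table"),
      mode = "full_partial")$matrix
  } else {
    stats::cor(R)
  }
  n <- ncol(C)
  ui <- .ut_cache(n)$i
  uj <- .ut_cache(n)$j
  absC <- abs(C[cbind(ui, uj)])
  o <- order(-absC, ui, uj)
  edges <- cbind(ui[o], uj[o]) - 1L
  kvec <- .edge_counts(grid, n)

  gm <- cpp_grid_metrics(edges, n, kvec, nodal, betweenness,
                         "Eloc" %in% want)
  glob <- gm$global
  res_glob <- glob[, intersect(c("Lp", "Eglob", "Eloc", "Cp"), want),
                   drop = FALSE]
  if (any(c("gamma", "lambda", "sigma") %in% want)) {
    stopifnot(n_null >= 1)
    gl <- matrix(NA_real_, length(grid), 3,
                 dimnames = list(NULL, c("gamma", "lambda", "sigma")))
    for (di in seq_along(grid)) {
      ek <- edges[seq_len(kvec[di]), , drop = FALSE]
      nulls <- if (is.null(null_seed)) {
        cpp_null_cp_lp(ek, n, as.integer(n_null), 10)
      } else {
        with_seed(derive_seed(null_seed, "null", di),
                  cpp_null_cp_lp(ek, n, as.integer(n_null), 10))
      }
      if (nulls$n_used == 0) next  # gamma/lambda undefined at this density
      g <- glob[di, "Cp"] / nulls$mean_cp
      l <- glob[di, "Lp"] / nulls$mean_lp
      gl[di, ] <- c(g, l, g / l)
    }
    res_glob <- cbind(res_glob,
                      gl[, intersect(colnames(gl), want), drop = FALSE])
  }
  out <- list(densities = grid, global = res_glob,
              unreachable_frac = glob[, "unreachable_frac"])
  if (nodal) {
    rownames(gm$nodal_efficiency) <- rownames(gm$degree) <- colnames(C)
    out$nodal_efficiency <- gm$nodal_efficiency
    out$degree <- gm$degree
  }
  if (betweenness) {
    rownames(gm$betweenness) <- colnames(C)
    out$betweenness <- gm$betweenness
  }
  out
}

# OLS residuals of Y on intercept + non-constant covariate columns
.residual_matrix <- function(Y, Craw) {
  n_sub <- nrow(Y)
  keep <- if (ncol(Craw) > 0) {
    apply(Craw, 2, function(x) stats::var(x) > 0)
  } else {
    logical(0)
  }
  X <- cbind(1, Craw[, keep, drop = FALSE])
  if (n_sub < ncol(X) + 2) {
    stop("too few subjects (", n_sub, ") for ", ncol(X) - 1, " covariate(s)")
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop("rank-deficient design; collinear covariate(s): ",
         paste(colnames(Craw)[keep], collapse = ", "))
  }
  qr.resid(qrX, Y)
}

# cached upper-triangle index pairs in the fixed lexicographic (i, j) order
.ut_env <- new.env(parent = emptyenv())
.ut_cache <- function(n) {
  key <- as.character(n)
  if (is.null(.ut_env[[key]])) {
    i <- rep(seq_len(n - 1), times = (n - 1):1)
    j <- unlist(lapply(seq_len(n - 1), function(a) seq(a + 1, n)))
    .ut_env[[key]] <- list(i = i, j = j)
  }
  .ut_env[[key]]
}

# data-frame front-end to .matrix_curves, with constant-covariate messages
.pipeline_curves <- function(df, config, grid,
                             want = c("Cp", "Lp", "Eglob", "Eloc"),
                             nodal = FALSE, betweenness = FALSE,
                             n_null = 0L, null_seed = NULL,
                             pooled_df = NULL, quiet = TRUE) {
  Y <- as.matrix(df[thalamic_nucleus_labels()])
  Craw <- .cov_matrix(df, config$covariates)
  if (!quiet && ncol(Craw) > 0) {
    const <- colnames(Craw)[apply(Craw, 2, function(x) stats::var(x) == 0)]
    for (cv in const) message("dropping constant covariate '", cv, "'")
  }
  resid <- NULL
  if (isTRUE(config$pooled_residualization)) {
    base <- if (is.null(pooled_df)) df else pooled_df
    R_all <- .residual_matrix(as.matrix(base[thalamic_nucleus_labels()]),
                              .cov_matrix(base, config$covariates))
    resid <- R_all[match(df$subject_id, base$subject_id), , drop = FALSE]
  }
  .matrix_curves(Y, Craw, config, grid, want = want, nodal = nodal,
                 betweenness = betweenness, n_null = n_null,
                 null_seed = null_seed, resid = resid)
}

#' Metric curve of one group over the sparsity grid
#'
#' Composes residualization, correlation-matrix construction, binarization at
#' each grid density and the requested global metric, returning the curve
#' together with its average value and trapezoid AUC (the two summary
#' columns of the standard global-network table).
#'
#' @param cohort a `"cohort_table"`.
#' @param group group label.
#' @param metric one of `"Cp"`, `"Lp"`, `"Eglob"`, `"Eloc"`, `"gamma"`,
#'   `"lambda"`, `"sigma"`.
#' @param config a [run_config()].
#' @return List of class `"metric_curve"`: `metric`, `group`, `densities`,
#'   `values`, `average`, `auc`.
#' @export
metric_curve <- function(cohort, group, metric, config = run_config()) {
  metric <- match.arg(metric, .global_metric_names)
  df <- as.data.frame(cohort)
  df <- df[df$group == group, , drop = FALSE]
  if (nrow(df) == 0) stop("no subjects in group ", group)
  grid <- density_grid(config)
  pc <- .pipeline_curves(
    df, config, grid, want = unique(c(metric, "Cp", "Lp")),
    n_null = config$n_null_networks,
    null_seed = derive_seed(config$rng_seed, "curve", group),
    pooled_df = as.data.frame(cohort), quiet = FALSE)
  vals <- pc$global[, metric]
  structure(list(metric = metric, group = group, densities = grid,
                 values = vals, average = mean(vals, na.rm = TRUE),
                 auc = auc_trapezoid(grid, vals)),
            class = "metric_curve")
}

#' @export
as.data.frame.metric_curve <- function(x, ...) {
  data.frame(metric = x$metric, group = x$group, density = x$densities,
             value = x$values, stringsAsFactors = FALSE, row.names = NULL)
}

#' Area under a stored metric curve
#'
#' @param curve a `"metric_curve"`.
#' @return Scalar trapezoid AUC recomputed from the stored points.
#' @export
curve_auc <- function(curve) {
  auc_trapezoid(curve$densities, curve$values)
}

#' Global metric curves for every group
#'
#' @param cohort a `"cohort_table"`.
#' @param config a [run_config()].
#' @param groups group labels (default: all present).
#' @param metrics global metric names (default: all seven).
#' @return List with `curves` (long data frame: metric, group, density,
#'   value) and `summary` (metric, group, average, auc).
#' @export
group_metric_curves <- function(cohort, config = run_config(),
                                groups = NULL,
                                metrics = .global_metric_names) {
  df <- as.data.frame(cohort)
  if (is.null(groups)) groups <- unique(df$group)
  grid <- density_grid(config)
  curves <- list()
  summ <- list()
  for (g in groups) {
    sub <- df[df$group == g, , drop = FALSE]
    pc <- .pipeline_curves(sub, config, grid,
                           want = unique(c(metrics, "Cp", "Lp")),
                           n_null = config$n_null_networks,
                           null_seed = derive_seed(config$rng_seed, "curve", g),
                           pooled_df = df, quiet = FALSE)
    for (m in metrics) {
      vals <- pc$global[, m]
      curves[[paste(g, m)]] <- data.frame(
        metric = m, group = g, density = grid, value = vals,
        stringsAsFactors = FALSE)
      summ[[paste(g, m)]] <- data.frame(
        metric = m, group = g, average = mean(vals, na.rm = TRUE),
        auc = auc_trapezoid(grid, vals), stringsAsFactors = FALSE)
    }
  }
  list(curves = do.call(rbind, c(curves, list(make.row.names = FALSE))),
       summary = do.call(rbind, c(summ, list(make.row.names = FALSE))))
}

# AUC summaries of one subject subset inside the permutation engine
.side_aucs <- function(Y, Craw, idx, config, grid, w, global, nodal,
                       n_null_perm, resid = NULL) {
  pc <- .matrix_curves(Y[idx, , drop = FALSE], Craw[idx, , drop = FALSE],
                       config, grid, want = unique(c(global, "Cp", "Lp")),
                       nodal = any(nodal %in% c("degree", "nodal_efficiency")),
                       betweenness = "betweenness" %in% nodal,
                       n_null = n_null_perm, null_seed = NULL,
                       resid = if (is.null(resid)) NULL else
                         resid[idx, , drop = FALSE])
  g_auc <- vapply(global, function(m) {
    suppressMessages(auc_trapezoid(grid, pc$global[, m]))
  }, 0)
  n_auc <- lapply(nodal, function(m) as.numeric(pc[[m]] %*% w))
  names(n_auc) <- nodal
  list(global = g_auc, nodal = n_auc)
}

#' Joint permutation tests on global and nodal AUCs
#'
#' Runs the between-group AUC permutation test for any set of global metrics
#' and nodal-metric families in one pass, with a single shared set of group
#' relabelings. Each permutation randomly reassigns the pooled subjects of
#' the two groups to pseudo-groups of the original sizes and reruns the
#' entire pipeline (residualization included). Two-sided p-values use the
#' add-one rule `p = (1 + #{|null| >= |obs|}) / (B + 1)`; each nodal family
#' is Benjamini-Hochberg adjusted across its 50 nodes.
#'
#' Relabelings are drawn from a stream derived from the root seed and the
#' *sorted* group labels, so swapping the group order negates observed
#' differences but leaves every p-value unchanged.
#'
#' @param cohort a `"cohort_table"`.
#' @param groups character vector of two group labels `(A, B)`.
#' @param config a [run_config()]; `n_permutations` sets B.
#' @param global_metrics global metric names to test (may be empty).
#' @param nodal_metrics nodal metric names to test (may be empty).
#' @param seed_tag internal tag separating the permutation streams of the
#'   wrapper functions.
#' @return List with `global`: one `"perm_result"` per global metric, and
#'   `nodal`: one data frame per nodal family (node, AUCs, difference, raw
#'   and BH-adjusted p, flag).
#' @export
permutation_tests <- function(cohort, groups, config = run_config(),
                              global_metrics = "Lp",
                              nodal_metrics = character(0),
                              seed_tag = "permtests") {
  stopifnot(length(groups) == 2, groups[1] != groups[2])
  global_metrics <- vapply(global_metrics, match.arg, "",
                           choices = .global_metric_names, USE.NAMES = FALSE)
  if (length(nodal_metrics) > 0) {
    nodal_metrics <- vapply(nodal_metrics, match.arg, "",
                            choices = .nodal_metric_names, USE.NAMES = FALSE)
  }
  df <- as.data.frame(cohort)
  grid <- density_grid(config)
  w <- .trapz_weights(grid)
  need_null <- any(c("gamma", "lambda", "sigma") %in% global_metrics)

  # observed statistics, full null-network count, per-group derived seeds
  obs <- lapply(groups, function(g) {
    sub <- df[df$group == g, , drop = FALSE]
    if (nrow(sub) == 0) stop("no subjects in group ", g)
    pc <- .pipeline_curves(
      sub, config, grid, want = unique(c(global_metrics, "Cp", "Lp")),
      nodal = any(nodal_metrics %in% c("degree", "nodal_efficiency")),
      betweenness = "betweenness" %in% nodal_metrics,
      n_null = config$n_null_networks,
      null_seed = derive_seed(config$rng_seed, "curve", g),
      pooled_df = df)
    list(
      global_auc = vapply(global_metrics, function(m) {
        suppressMessages(auc_trapezoid(grid, pc$global[, m]))
      }, 0),
      global_avg = vapply(global_metrics, function(m) {
        mean(pc$global[, m], na.rm = TRUE)
      }, 0),
      nodal_auc = {
        na <- lapply(nodal_metrics, function(m) as.numeric(pc[[m]] %*% w))
        names(na) <- nodal_metrics
        na
      }
    )
  })
  names(obs) <- groups

  gs <- sort(groups)
  sgn <- if (identical(groups[1], gs[1])) 1 else -1
  obs_g_sorted <- sgn * (obs[[groups[1]]]$global_auc -
                           obs[[groups[2]]]$global_auc)
  obs_n_sorted <- lapply(nodal_metrics, function(m) {
    sgn * (obs[[groups[1]]]$nodal_auc[[m]] - obs[[groups[2]]]$nodal_auc[[m]])
  })
  names(obs_n_sorted) <- nodal_metrics

  pooled <- df[df$group %in% groups, , drop = FALSE]
  Y <- as.matrix(pooled[thalamic_nucleus_labels()])
  Craw <- .cov_matrix(pooled, config$covariates)
  resid_pool <- NULL
  if (isTRUE(config$pooled_residualization)) {
    R_all <- .residual_matrix(as.matrix(df[thalamic_nucleus_labels()]),
                              .cov_matrix(df, config$covariates))
    resid_pool <- R_all[match(pooled$subject_id, df$subject_id), ,
                        drop = FALSE]
  }
  n1 <- sum(pooled$group == gs[1])
  n_tot <- nrow(pooled)
  B <- config$n_permutations
  n_null_perm <- if (need_null) config$n_null_networks_perm else 0L

  seed0 <- derive_seed(config$rng_seed, seed_tag,
                       paste(global_metrics, collapse = ","),
                       paste(nodal_metrics, collapse = ","),
                       paste(gs, collapse = "|"))
  null_global <- matrix(NA_real_, B, length(global_metrics),
                        dimnames = list(NULL, global_metrics))
  exceed_nodal <- lapply(nodal_metrics, function(m) integer(50))
  names(exceed_nodal) <- nodal_metrics
  with_seed(seed0, {
    for (b in seq_len(B)) {
      sel <- sample.int(n_tot, n1)
      s1 <- .side_aucs(Y, Craw, sel, config, grid, w, global_metrics,
                       nodal_metrics, n_null_perm, resid = resid_pool)
      s2 <- .side_aucs(Y, Craw, seq_len(n_tot)[-sel], config, grid, w,
                       global_metrics, nodal_metrics, n_null_perm,
                       resid = resid_pool)
      null_global[b, ] <- s1$global - s2$global
      for (m in nodal_metrics) {
        exceed_nodal[[m]] <- exceed_nodal[[m]] +
          (abs(s1$nodal[[m]] - s2$nodal[[m]]) >= abs(obs_n_sorted[[m]]))
      }
    }
  })

  global_out <- lapply(global_metrics, function(m) {
    nulls <- null_global[, m]
    p <- (1 + sum(abs(nulls) >= abs(obs_g_sorted[[m]]), na.rm = TRUE)) /
      (B + 1)
    structure(list(
      metric = m, groups = groups,
      average = stats::setNames(c(obs[[groups[1]]]$global_avg[[m]],
                                  obs[[groups[2]]]$global_avg[[m]]), groups),
      auc = stats::setNames(c(obs[[groups[1]]]$global_auc[[m]],
                              obs[[groups[2]]]$global_auc[[m]]), groups),
      observed_diff_average = obs[[groups[1]]]$global_avg[[m]] -
        obs[[groups[2]]]$global_avg[[m]],
      observed_diff_auc = obs[[groups[1]]]$global_auc[[m]] -
        obs[[groups[2]]]$global_auc[[m]],
      p = p, n_permutations = B,
      null_mean = mean(nulls, na.rm = TRUE),
      null_sd = stats::sd(nulls[!is.na(nulls)]),
      n_null_networks_perm = if (need_null) n_null_perm else NA_integer_
    ), class = "perm_result")
  })
  names(global_out) <- global_metrics

  nodes <- thalamic_nucleus_labels()
  nodal_out <- lapply(nodal_metrics, function(m) {
    p <- (1 + exceed_nodal[[m]]) / (B + 1)
    p_fdr <- bh_fdr(p)
    data.frame(
      node = nodes, metric = m,
      auc_A = obs[[groups[1]]]$nodal_auc[[m]],
      auc_B = obs[[groups[2]]]$nodal_auc[[m]],
      diff_auc = obs[[groups[1]]]$nodal_auc[[m]] -
        obs[[groups[2]]]$nodal_auc[[m]],
      p = p, p_fdr = p_fdr, sig = p_fdr < config$fdr_alpha,
      stringsAsFactors = FALSE, row.names = NULL)
  })
  names(nodal_out) <- nodal_metrics

  list(global = global_out, nodal = nodal_out)
}

#' Permutation test on the AUC of one global metric
#'
#' Observed statistic: `AUC(group A) - AUC(group B)` of the metric curve,
#' tested against the permutation null of [permutation_tests()]. For
#' gamma/lambda/sigma each permutation uses the reduced
#' `n_null_networks_perm` null-network count; the observed curves always use
#' the full `n_null_networks`.
#'
#' @param cohort a `"cohort_table"`.
#' @param groups character vector of two group labels `(A, B)`.
#' @param metric global metric name.
#' @param config a [run_config()]; `n_permutations` sets B.
#' @return List of class `"perm_result"`.
#' @export
permutation_group_difference <- function(cohort, groups, metric,
                                         config = run_config()) {
  metric <- match.arg(metric, .global_metric_names)
  permutation_tests(cohort, groups, config, global_metrics = metric,
                    nodal_metrics = character(0),
                    seed_tag = "permtest")$global[[metric]]
}

#' Per-node permutation tests with FDR for a nodal metric
#'
#' Computes each node's metric AUC over the sparsity grid in both groups and
#' permutation-tests the 50 per-node AUC differences. All nodes share one
#' set of group relabelings (preserving inter-node dependence under the FDR
#' adjustment and reducing cost); the 50 raw p-values are
#' Benjamini-Hochberg adjusted and nodes are flagged where the adjusted p is
#' below `config$fdr_alpha`.
#'
#' @param cohort a `"cohort_table"`.
#' @param groups character vector of two group labels `(A, B)`.
#' @param metric `"degree"`, `"nodal_efficiency"` or `"betweenness"`.
#' @param config a [run_config()].
#' @return Data frame with one row per node: observed AUCs, difference, raw
#'   p, BH-adjusted p, and significance flag.
#' @export
nodal_family_test <- function(cohort, groups, metric, config = run_config()) {
  metric <- match.arg(metric, .nodal_metric_names)
  permutation_tests(cohort, groups, config, global_metrics = character(0),
                    nodal_metrics = metric,
                    seed_tag = "nodalperm")$nodal[[metric]]
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: monotone, capped at 1, original order restored.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_fdr <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}
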