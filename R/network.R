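#' Residualize nucleus volumes against covariates
#'
#' Per-region ordinary least squares of the absolute volumes on an intercept
#' plus the retained covariates (default age, sex, lesion load), within one
#' group. Sex enters the design as 0 = female, 1 = male. Covariates that are
#' constant within the group (e.g. lesion volume in controls) are dropped with
#' a message. The residuals replace the raw volumes for all downstream
#' correlation analysis.
#'
#' @param cohort a `"cohort_table"`.
#' @param group group label, or `NULL` to use all rows (pooled).
#' @param covariates covariate column names; empty vector gives mean-centering
#'   only.
#' @return List of class `"residual_table"` with elements `group`,
#'   `residuals` (subjects x 50 matrix), `covariates_used`, `subject_id`.
#' @export
residualize <- function(cohort, group = NULL,
                        covariates = c("age", "sex", "lesion_volume")) {
  df <- as.data.frame(cohort)
  if (!is.null(group)) {
    df <- df[df$group == group, , drop = FALSE]
    if (nrow(df) == 0) stop("no subjects in group ", group)
  }
  X <- .design_matrix(df, covariates)
  if (nrow(df) < ncol(X) + 1) {
    stop("group has too few subjects (", nrow(df), ") for ",
         ncol(X) - 1, " covariate(s)")
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, ncol(X))]]
    stop("rank-deficient design; collinear covariate(s): ",
         paste(dropped, collapse = ", "))
  }
  Y <- as.matrix(df[thalamic_nucleus_labels()])
  res <- qr.resid(qrX, Y)
  structure(list(group = if (is.null(group)) "all" else group,
                 residuals = res,
                 covariates_used = setdiff(colnames(X), "(Intercept)"),
                 subject_id = df$subject_id),
            class = "residual_table")
}

# intercept + covariates design; constant covariates dropped with a message
.design_matrix <- function(df, covariates) {
  X <- matrix(1, nrow(df), 1, dimnames = list(NULL, "(Intercept)"))
  for (cv in covariates) {
    if (!cv %in% names(df)) stop("no such covariate column: ", cv)
    x <- df[[cv]]
    if (cv == "sex") x <- as.numeric(x == "male")
    x <- as.numeric(x)
    if (anyNA(x)) stop("missing values in covariate ", cv)
    if (stats::sd(x) == 0) {
      message("dropping constant covariate '", cv, "'")
      next
    }
    X <- cbind(X, x)
    colnames(X)[ncol(X)] <- cv
  }
  X
}

#' Build a group's inter-nucleus correlation network
#'
#' Forms the symmetric 50 x 50 matrix of inter-regional association
#' coefficients from covariate-residualized volumes. The default
#' `residual_pearson` mode is the product-moment correlation of each pair of
#' residual columns (i.e. correlation partialling out the regressed
#' covariates). `full_partial` computes pairwise partial correlations from a
#' shrinkage-regularized precision matrix of the residuals
#' (`-omega_ij / sqrt(omega_ii omega_jj)`, with the correlation matrix shrunk
#' toward the identity before inversion); it conditions every pair on all
#' other 48 regions and is offered for sensitivity analysis. The diagonal is
#' defined as 0.
#'
#' @param res a `"residual_table"` from [residualize()].
#' @param mode `"residual_pearson"` (default) or `"full_partial"`.
#' @param shrinkage shrinkage intensity toward the identity in `full_partial`
#'   mode; `NULL` (default) uses the analytic variance-minimizing estimate,
#'   a number in `[0, 1]` fixes it.
#' @return List of class `"group_network"` with `group`, `nodes`, `matrix`.
#' @export
build_correlation_matrix <- function(res,
                                     mode = c("residual_pearson",
                                              "full_partial"),
                                     shrinkage = NULL) {
  mode <- match.arg(mode)
  R <- res$residuals
  if (nrow(R) < 4) stop("need at least 4 subjects to correlate")
  sds <- apply(R, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance residuals for region(s): ",
         paste(colnames(R)[sds == 0], collapse = ", "))
  }
  S <- stats::cor(R)
  if (mode == "full_partial") {
    lam <- if (is.null(shrinkage)) .shrinkage_intensity(R) else shrinkage
    Sh <- (1 - lam) * S + lam * diag(ncol(S))
    Om <- solve(Sh)
    d <- sqrt(diag(Om))
    S <- -Om / tcrossprod(d)
  }
  diag(S) <- 0
  structure(list(group = res$group, nodes = colnames(R), matrix = S,
                 mode = mode),
            class = "group_network")
}

# analytic shrinkage intensity toward the identity target for a correlation
# matrix (variance-minimizing linear shrinkage on the off-diagonal entries)
.shrinkage_intensity <- function(R) {
  n <- nrow(R)
  Xs <- scale(R) / sqrt(n - 1)       # so crossprod(Xs) = cor(R)
  S <- crossprod(Xs)
  # var of each r_ij estimated from the per-subject products
  W2 <- crossprod(Xs^2) * n          # sum_k w_kij^2 scaled
  varr <- n / (n - 1)^2 * (W2 - S^2)
  off <- upper.tri(S)
  lam <- sum(varr[off]) / sum(S[off]^2)
  min(1, max(0, lam))
}

#' Sparsity (density) grid
#'
#' Arithmetic grid of network densities, inclusive of both endpoints when the
#' step divides the range; otherwise truncated below the maximum with a
#' message. The default 0.05-0.40 grid in 0.01 steps has 36 values.
#'
#' @param config a [run_config()].
#' @return Numeric vector of densities.
#' @export
density_grid <- function(config = run_config()) {
  lo <- config$sparsity_min
  hi <- config$sparsity_max
  st <- config$sparsity_step
  m <- floor((hi - lo) / st + 1e-9)
  grid <- lo + st * seq(0, m)
  if (abs(grid[length(grid)] - hi) > 1e-9) {
    message("sparsity_step does not divide the range; grid truncated at ",
            format(grid[length(grid)]))
  }
  grid
}

# rank the N(N-1)/2 node pairs by decreasing |C|, ties broken by the fixed
# lexicographic (i, j) pair order; returns a K x 2 integer matrix
.rank_edges <- function(C) {
  n <- nrow(C)
  idx <- which(upper.tri(C))
  i <- ((idx - 1) %% n) + 1
  j <- ((idx - 1) %/% n) + 1
  o <- order(-abs(C[idx]), i, j)
  cbind(i = i[o], j = j[o])
}

# edge counts for a density vector (round half away from zero)
.edge_counts <- function(d, n_nodes) {
  as.integer(round_half_up(d * n_nodes * (n_nodes - 1) / 2))
}

#' Binarize a correlation network at a target density
#'
#' Rank thresholding on the absolute correlation: the `k = round(d * N(N-1)/2)`
#' node pairs with the largest `|C_ij|` receive an edge (rounding half away
#' from zero; ties at the cutoff broken by the fixed lexicographic pair
#' order). Rank thresholding guarantees equal edge counts across groups at
#' each grid density, which the AUC comparison requires.
#'
#' @param net a `"group_network"`.
#' @param d density in (0, 1).
#' @return List of class `"binary_adjacency"` with `nodes`, `matrix` (0/1),
#'   `density`, `n_edges`.
#' @export
binarize_at_density <- function(net, d) {
  stopifnot(d > 0, d < 1)
  n <- length(net$nodes)
  k <- .edge_counts(d, n)
  if (k == 0) stop("density ", d, " yields an empty graph")
  edges <- .rank_edges(net$matrix)[seq_len(k), , drop = FALSE]
  A <- matrix(0L, n, n, dimnames = list(net$nodes, net$nodes))
  A[edges] <- 1L
  A[edges[, c(2, 1), drop = FALSE]] <- 1L
  structure(list(nodes = net$nodes, matrix = A, density = d, n_edges = k),
            class = "binary_adjacency")
}

# coerce adjacency input (binary_adjacency or plain 0/1 matrix) to a 0-based
# edge matrix plus node count, for the C++ core
.adj_edges <- function(A) {
  if (inherits(A, "binary_adjacency")) A <- A$matrix
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  if (any(A != t(A))) stop("adjacency matrix must be symmetric")
  if (any(diag(A) != 0)) stop("adjacency matrix must have a zero diagonal")
  idx <- which(upper.tri(A) & A != 0)
  n <- nrow(A)
  i <- ((idx - 1) %% n) + 1
  j <- ((idx - 1) %/% n) + 1
  list(edges = cbind(i, j) - 1L, n = n,
       nodes = if (!is.null(rownames(A))) rownames(A) else as.character(seq_len(n)))
}
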