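# Independent brute-force oracles and small fixtures used across the suite.
# The oracles deliberately avoid the package's own code paths: distances via
# Floyd-Warshall, path counts via adjacency-matrix powers, statistics via
# hand-expanded formulas.

# --- tiny graph builders ---------------------------------------------------

adj_from_edges <- function(n, edges) {
  A <- matrix(0L, n, n)
  for (e in edges) {
    A[e[1], e[2]] <- 1L
    A[e[2], e[1]] <- 1L
  }
  A
}

complete_graph <- function(n) {
  A <- matrix(1L, n, n)
  diag(A) <- 0L
  A
}

cycle_graph <- function(n) {
  adj_from_edges(n, lapply(seq_len(n), function(i) c(i, i %% n + 1)))
}

path_graph <- function(n) {
  adj_from_edges(n, lapply(seq_len(n - 1), function(i) c(i, i + 1)))
}

star_graph <- function(k) { # hub = node 1, k leaves
  adj_from_edges(k + 1, lapply(seq_len(k), function(i) c(1, i + 1)))
}

rand_adj <- function(n, p = 0.4) {
  A <- matrix(0L, n, n)
  ut <- which(upper.tri(A))
  on <- ut[stats::runif(length(ut)) < p]
  A[on] <- 1L
  A + t(A)
}

# Watts-Strogatz ring lattice: n nodes, k neighbours each side, rewiring prob p
ws_adj <- function(n, k, p) {
  A <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    for (d in seq_len(k)) {
      j <- (i + d - 1) %% n + 1
      A[i, j] <- A[j, i] <- 1L
    }
  }
  ut <- which(upper.tri(A) & A == 1L)
  for (idx in ut) {
    if (stats::runif(1) < p) {
      i <- ((idx - 1) %% n) + 1
      j <- ((idx - 1) %/% n) + 1
      free <- which(A[i, ] == 0L)
      free <- setdiff(free, i)
      if (length(free) > 0) {
        t_ <- free[sample.int(length(free), 1)]
        A[i, j] <- A[j, i] <- 0L
        A[i, t_] <- A[t_, i] <- 1L
      }
    }
  }
  A
}

# --- graph-metric oracles --------------------------------------------------

oracle_floyd_warshall <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[A != 0] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

oracle_clustering <- function(A) {
  n <- nrow(A)
  cc <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(A[v, ] != 0)
    d <- length(nb)
    if (d < 2) next
    links <- 0
    for (a in seq_len(d - 1)) {
      for (b in seq(a + 1, d)) {
        if (A[nb[a], nb[b]] != 0) links <- links + 1
      }
    }
    cc[v] <- 2 * links / (d * (d - 1))
  }
  cc
}

# shortest-path counts via adjacency-matrix powers: walks of the minimal
# length between two nodes are exactly the shortest paths
oracle_path_counts <- function(A, D) {
  n <- nrow(A)
  maxd <- max(D[is.finite(D)])
  pows <- vector("list", maxd)
  P <- diag(n)
  for (L in seq_len(max(1, maxd))) {
    P <- P %*% A
    pows[[L]] <- P
  }
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    for (t in seq_len(n)) {
      if (s != t && is.finite(D[s, t])) sigma[s, t] <- pows[[D[s, t]]][s, t]
    }
  }
  sigma
}

oracle_betweenness <- function(A) {
  D <- oracle_floyd_warshall(A)
  sigma <- oracle_path_counts(A, D)
  n <- nrow(A)
  cb <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n)) {
      for (t in seq_len(n)) {
        if (s >= t || s == v || t == v) next
        if (!is.finite(D[s, t]) || sigma[s, t] == 0) next
        if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
            D[s, v] + D[v, t] == D[s, t]) {
          cb[v] <- cb[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
  }
  cb
}

oracle_global_efficiency <- function(A) {
  D <- oracle_floyd_warshall(A)
  inv <- 1 / D
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (nrow(A) * (nrow(A) - 1))
}

oracle_local_efficiency <- function(A) {
  n <- nrow(A)
  vals <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(A[v, ] != 0)
    if (length(nb) < 2) next
    vals[v] <- oracle_global_efficiency(A[nb, nb, drop = FALSE])
  }
  mean(vals)
}

oracle_lp <- function(A) {
  D <- oracle_floyd_warshall(A)
  off <- D[row(D) != col(D)]
  mean(off[is.finite(off)])
}

# --- statistics oracles ----------------------------------------------------

oracle_ols_residuals <- function(X, Y) {
  beta <- solve(t(X) %*% X, t(X) %*% Y)
  Y - X %*% beta
}

oracle_anova_f <- function(values, groups) {
  groups <- as.factor(groups)
  gm <- tapply(values, groups, mean)
  ns <- tapply(values, groups, length)
  grand <- mean(values)
  ssb <- sum(ns * (gm - grand)^2)
  ssw <- sum((values - gm[groups])^2)
  k <- nlevels(groups)
  (ssb / (k - 1)) / (ssw / (length(values) - k))
}

oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

oracle_spearman <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

oracle_trapezoid <- function(x, y) {
  s <- 0
  for (i in seq_len(length(x) - 1)) {
    s <- s + 0.5 * (y[i] + y[i + 1]) * (x[i + 1] - x[i])
  }
  s
}

# --- fixtures --------------------------------------------------------------

# small three-group cohort; deterministic given seed
small_cohort <- function(seed = 1, n = c(8, 8, 10)) {
  spec <- synthetic_cohort_spec(n_fms = n[1], n_nfms = n[2], n_hc = n[3])
  generate_cohort(spec, seed = seed)
}

# hand-built minimal cohort data frame (3 subjects, one per group)
tiny_cohort_df <- function() {
  labs <- thalamic_nucleus_labels()
  df <- data.frame(
    subject_id = c("s1", "s2", "s3"),
    group = c("F-MS", "NF-MS", "HC"),
    age = c(30, 28, 35),
    sex = c("female", "male", "female"),
    lesion_volume = c(5.2, 6.1, 0),
    eTIV = c(1300, 1350, 1400),
    disease_duration = c(2.5, 1.5, NA),
    stringsAsFactors = FALSE, check.names = FALSE
  )
  vols <- matrix(rep(seq(0.1, 5, length.out = 50), each = 3), nrow = 3)
  colnames(vols) <- labs
  cbind(df, as.data.frame(vols, check.names = FALSE))
}
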