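#' Graph metrics on a binary adjacency
#'
#' All metrics operate on unweighted, undirected graphs given as a
#' `"binary_adjacency"` (from [binarize_at_density()]) or a plain symmetric
#' 0/1 matrix with zero diagonal. Conventions for disconnected graphs: the
#' characteristic path length averages finite distances only (the fraction of
#' unreachable pairs is reported alongside), while the efficiency metrics use
#' `1/Inf = 0`.
#'
#' @name graph-metrics
NULL

#' All-pairs shortest-path (hop) distances
#'
#' @param A adjacency (see [graph-metrics]).
#' @return Symmetric numeric matrix of breadth-first hop distances, `Inf` for
#'   unreachable pairs, zero diagonal.
#' @export
shortest_path_distances <- function(A) {
  g <- .adj_edges(A)
  D <- cpp_bfs_distances(g$edges, g$n)
  dimnames(D) <- list(g$nodes, g$nodes)
  D
}

#' Clustering coefficient
#'
#' Per node, the fraction of its neighbour pairs that are themselves
#' connected (`2 t_v / (k_v (k_v - 1))`); nodes with degree < 2 contribute 0.
#'
#' @param A adjacency.
#' @return List with `per_node` (named vector) and `Cp` (unweighted mean).
#' @export
clustering_coefficient <- function(A) {
  g <- .adj_edges(A)
  cc <- as.numeric(cpp_clustering(g$edges, g$n))
  names(cc) <- g$nodes
  list(per_node = cc, Cp = mean(cc))
}

#' Characteristic path length
#'
#' Mean of the finite off-diagonal shortest-path distances over reachable
#' ordered pairs. Errors when the graph has no finite distance at all.
#'
#' @param A adjacency.
#' @return List with `Lp` and `unreachable_frac`, the fraction of ordered
#'   node pairs with no connecting path.
#' @export
characteristic_path_length <- function(A) {
  D <- shortest_path_distances(A)
  off <- D[row(D) != col(D)]
  fin <- is.finite(off)
  if (!any(fin)) stop("Lp undefined: no finite path between any node pair")
  list(Lp = mean(off[fin]), unreachable_frac = mean(!fin))
}

#' Global efficiency
#'
#' Mean over all ordered node pairs of the inverse shortest-path distance,
#' with `1/Inf = 0`.
#'
#' @param A adjacency.
#' @return Scalar in `[0, 1]`.
#' @export
global_efficiency <- function(A) {
  D <- shortest_path_distances(A)
  inv <- 1 / D
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (nrow(D) * (nrow(D) - 1))
}

#' Local efficiency
#'
#' Per node, the global efficiency of the subgraph induced by its neighbours
#' (0 for fewer than 2 neighbours); returned as the mean over all nodes.
#'
#' @param A adjacency.
#' @return Scalar in `[0, 1]`.
#' @export
local_efficiency <- function(A) {
  g <- .adj_edges(A)
  cpp_local_efficiency(g$edges, g$n)
}

#' Nodal efficiency
#'
#' Mean inverse distance from a node to all other nodes (`1/Inf = 0`).
#'
#' @param A adjacency.
#' @param v node name or index; `NULL` (default) returns all nodes.
#' @return Named numeric vector (or scalar when `v` is given).
#' @export
nodal_efficiency <- function(A, v = NULL) {
  D <- shortest_path_distances(A)
  inv <- 1 / D
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  eff <- rowSums(inv) / (nrow(D) - 1)
  if (is.null(v)) eff else unname(eff[v])
}

#' Nodal degree
#'
#' @param A adjacency.
#' @return Named integer vector of edge counts per node.
#' @export
nodal_degree <- function(A) {
  if (inherits(A, "binary_adjacency")) A <- A$matrix
  deg <- as.integer(rowSums(A != 0))
  names(deg) <- rownames(A)
  deg
}

#' Betweenness centrality
#'
#' Fractional (tie-splitting) shortest-path betweenness, unnormalized, on the
#' unordered-pair convention (ordered-pair sums halved).
#'
#' @param A adjacency.
#' @return Named numeric vector.
#' @export
betweenness_centrality <- function(A) {
  g <- .adj_edges(A)
  b <- as.numeric(cpp_betweenness(g$edges, g$n))
  names(b) <- g$nodes
  b
}

#' Degree-preserving rewiring (randomized null network)
#'
#' Maslov-Sneppen double-edge swaps: pairs of edges are repeatedly selected
#' and their endpoints exchanged, rejecting any swap that would create a
#' self-loop or multi-edge, so the degree of every node is preserved exactly.
#'
#' @param A adjacency.
#' @param n_swaps number of attempted swaps; default 10 x edge count.
#' @param seed optional integer seed for this call.
#' @return A `"binary_adjacency"`-like list with the rewired `matrix`; if no
#'   swap could be applied the input is returned with a warning.
#' @export
rewire_preserving_degree <- function(A, n_swaps = NULL, seed = NULL) {
  g <- .adj_edges(A)
  if (nrow(g$edges) < 2) stop("need at least 2 edges to rewire")
  if (is.null(n_swaps)) n_swaps <- 10L * nrow(g$edges)
  run <- function() cpp_rewire(g$edges, g$n, as.integer(n_swaps))
  out <- if (is.null(seed)) run() else with_seed(seed, run())
  if (out$accepted == 0) {
    warning("no valid degree-preserving swap found; returning input graph")
  }
  M <- matrix(0L, g$n, g$n, dimnames = list(g$nodes, g$nodes))
  e <- out$edges + 1L
  M[e] <- 1L
  M[e[, c(2, 1), drop = FALSE]] <- 1L
  structure(list(nodes = g$nodes, matrix = M,
                 density = nrow(e) / (g$n * (g$n - 1) / 2),
                 n_edges = nrow(e)),
            class = "binary_adjacency")
}

#' Normalized small-world metrics
#'
#' gamma = Cp / mean Cp of the nulls, lambda = Lp / mean Lp of the nulls,
#' sigma = gamma / lambda, where the nulls are degree-preserving rewired
#' networks of the observed graph. Nulls whose Lp is undefined (no finite
#' distance) are excluded from the means and counted.
#'
#' @param A adjacency.
#' @param n_null number of null networks (default 200).
#' @param seed integer seed for the null stream.
#' @param swap_mult attempted swaps per null, as a multiple of the edge count.
#' @return List with `gamma`, `lambda`, `sigma`, `Cp`, `Lp`, `Cp_rand`,
#'   `Lp_rand`, `n_null_used`, `n_null_undefined`.
#' @export
normalized_small_world <- function(A, n_null = 200L, seed = 1L,
                                   swap_mult = 10) {
  g <- .adj_edges(A)
  obs_cp <- clustering_coefficient(A)$Cp
  obs_lp <- characteristic_path_length(A)$Lp
  nulls <- with_seed(seed,
    cpp_null_cp_lp(g$edges, g$n, as.integer(n_null), swap_mult))
  if (nulls$n_used == 0) stop("all null networks had undefined Lp")
  gamma <- obs_cp / nulls$mean_cp
  lambda <- obs_lp / nulls$mean_lp
  list(gamma = gamma, lambda = lambda, sigma = gamma / lambda,
       Cp = obs_cp, Lp = obs_lp,
       Cp_rand = nulls$mean_cp, Lp_rand = nulls$mean_lp,
       n_null_used = nulls$n_used, n_null_undefined = nulls$n_undefined)
}

#' Global metrics of one binary network
#'
#' Convenience wrapper returning Cp, Lp, Eglob, Eloc and, when `n_null > 0`,
#' gamma/lambda/sigma from degree-preserving nulls.
#'
#' @param A adjacency.
#' @param n_null null networks for the normalized metrics; 0 skips them.
#' @param seed seed for the null stream.
#' @return Named list of metric values plus `unreachable_frac`.
#' @export
global_metrics <- function(A, n_null = 0L, seed = 1L) {
  cl <- characteristic_path_length(A)
  out <- list(Cp = clustering_coefficient(A)$Cp, Lp = cl$Lp,
              Eglob = global_efficiency(A), Eloc = local_efficiency(A),
              unreachable_frac = cl$unreachable_frac)
  if (n_null > 0) {
    sw <- normalized_small_world(A, n_null = n_null, seed = seed)
    out$gamma <- sw$gamma
    out$lambda <- sw$lambda
    out$sigma <- sw$sigma
    out$n_null_used <- sw$n_null_used
  }
  out
}
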