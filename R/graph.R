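#' Validate a weighted adjacency matrix
#'
#' Checks symmetry and non-negativity, forces a zero diagonal, and attaches
#' node labels. Connectivity matrices are used unthresholded: every pairwise
#' weight is retained as an edge.
#'
#' @param w Square symmetric non-negative matrix.
#' @param node_labels Optional node names.
#' @return Numeric matrix with zero diagonal and dimnames.
#' @export
as_weighted_graph <- function(w, node_labels = rownames(w)) {
  w <- unclass(w)
  stopifnot(is.matrix(w), nrow(w) == ncol(w))
  if (any(w < 0)) stop("edge weights must be non-negative")
  if (max(abs(w - t(w))) > 1e-10) stop("adjacency matrix must be symmetric")
  w <- (w + t(w)) / 2
  diag(w) <- 0
  if (!is.null(node_labels)) dimnames(w) <- list(node_labels, node_labels)
  w
}

#' Weighted clustering coefficient (geometric triangle intensity)
#'
#' Onnela's form: with weights rescaled by the network maximum,
#' `C_i = (1 / (k_i (k_i - 1))) * sum_{j,h} (w_ij w_ih w_jh)^(1/3)` where
#' `k_i` counts nonzero neighbours. Nodes with fewer than two neighbours
#' have no triangles and get 0; the network average is taken over nodes
#' with `k_i >= 2`.
#'
#' @param w Weighted adjacency matrix.
#' @return List with `per_node` vector and `average`.
#' @export
clustering_weighted <- function(w) {
  w <- as_weighted_graph(w)
  n <- nrow(w)
  if (n < 3) stop("clustering requires at least 3 nodes")
  mx <- max(w)
  if (mx == 0) return(list(per_node = stats::setNames(rep(0, n), rownames(w)),
                           average = 0))
  wh <- (w / mx)^(1 / 3)
  cyc3 <- diag(wh %*% wh %*% wh)
  k <- rowSums(w > 0)
  c_i <- ifelse(k >= 2, cyc3 / (k * (k - 1)), 0)
  names(c_i) <- rownames(w)
  list(per_node = c_i,
       average = if (any(k >= 2)) mean(c_i[k >= 2]) else 0)
}

#' All-pairs shortest path lengths with inverse-weight edge lengths
#'
#' Edge length is `1 / weight` (a zero weight is an absent edge); distances
#' come from Dijkstra's algorithm on the resulting non-negative lengths.
#' Unreachable pairs are `Inf`.
#'
#' @param w Weighted adjacency matrix.
#' @return Symmetric distance matrix, zero diagonal.
#' @export
shortest_path_lengths <- function(w) {
  w <- as_weighted_graph(w)
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  len <- 1 / igraph::E(g)$weight
  d <- igraph::distances(g, weights = len, algorithm = "dijkstra")
  dimnames(d) <- dimnames(w)
  d
}

#' Characteristic path length
#'
#' Mean of the finite off-diagonal shortest-path distances; disconnected
#' pairs are excluded and their count reported via the `n_infinite`
#' attribute.
#'
#' @param w Weighted adjacency matrix.
#' @return Scalar with attribute `n_infinite` (unordered pairs excluded).
#' @export
characteristic_path_length <- function(w) {
  d <- shortest_path_lengths(w)
  v <- d[upper.tri(d)]
  fin <- v[is.finite(v)]
  if (!length(fin)) stop("all node pairs are disconnected")
  structure(mean(fin), n_infinite = sum(!is.finite(v)))
}

#' Global efficiency
#'
#' Mean over node pairs of the inverse shortest-path distance, with
#' `1 / Inf = 0` for disconnected pairs.
#'
#' @param w Weighted adjacency matrix.
#' @return Scalar in `[0, max weight]`.
#' @export
global_efficiency <- function(w) {
  d <- shortest_path_lengths(w)
  v <- d[upper.tri(d)]
  mean(ifelse(is.finite(v), 1 / v, 0))
}

#' Local efficiency
#'
#' Per node, the global efficiency of the subgraph induced on its
#' neighbours (weights restricted to that subgraph); 0 for nodes with
#' fewer than two neighbours.
#'
#' @param w Weighted adjacency matrix.
#' @return Named per-node vector.
#' @export
local_efficiency <- function(w) {
  w <- as_weighted_graph(w)
  n <- nrow(w)
  out <- stats::setNames(numeric(n), rownames(w))
  for (i in seq_len(n)) {
    nb <- which(w[i, ] > 0)
    if (length(nb) >= 2)
      out[i] <- global_efficiency(w[nb, nb, drop = FALSE])
  }
  out
}

#' Eigenvector centrality by power iteration
#'
#' Leading eigenvector of the raw weight matrix, Perron sign convention
#' (all entries non-negative), unit Euclidean norm. On a disconnected
#' graph the dominant (largest) component is used and the remaining nodes
#' get 0, with a warning.
#'
#' @param w Weighted adjacency matrix.
#' @param tol Relative convergence tolerance.
#' @param max_iter Iteration cap; non-convergence is an error.
#' @return Named non-negative vector with unit Euclidean norm.
#' @export
eigenvector_centrality <- function(w, tol = 1e-10, max_iter = 10000) {
  w <- as_weighted_graph(w)
  n <- nrow(w)
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(w > 0, mode = "undirected"))
  active <- seq_len(n)
  if (comp$no > 1) {
    warning("graph is disconnected; eigenvector centrality computed on the ",
            "dominant component, zeros elsewhere")
    active <- which(comp$membership == which.max(comp$csize))
  }
  a <- w[active, active, drop = FALSE]
  # positive diagonal shift: leaves eigenvectors untouched but breaks the
  # +/-lambda symmetry of bipartite graphs that stalls plain power iteration
  shift <- max(a)
  diag(a) <- diag(a) + shift
  v <- rep(1 / sqrt(length(active)), length(active))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    nv <- as.vector(a %*% v)
    nrm <- sqrt(sum(nv^2))
    if (nrm == 0) break                          # edgeless component
    nv <- nv / nrm
    if (max(abs(nv - v)) <= tol * max(abs(v))) {
      v <- nv
      converged <- TRUE
      break
    }
    v <- nv
  }
  if (!converged && max(w) > 0)
    stop("power iteration did not converge within ", max_iter, " iterations")
  out <- stats::setNames(numeric(n), rownames(w))
  out[active] <- abs(v)
  out / sqrt(sum(out^2))
}

#' All global and nodal network metrics for one weighted graph
#'
#' @param w Weighted adjacency matrix (e.g. a WPLI matrix).
#' @return A `network_metrics` list: `avg_clustering`, `char_path_length`,
#'   `global_efficiency` (global scalars), `local_efficiency`,
#'   `eigenvector_centrality` (per-node vectors).
#' @export
network_metrics <- function(w) {
  w <- as_weighted_graph(w)
  cl <- clustering_weighted(w)
  structure(list(
    avg_clustering = cl$average,
    char_path_length = as.numeric(characteristic_path_length(w)),
    global_efficiency = global_efficiency(w),
    local_efficiency = local_efficiency(w),
    eigenvector_centrality = eigenvector_centrality(w)),
    class = "network_metrics")
}
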