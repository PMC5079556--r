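#' Build the directed weighted fire-spread network
#'
#' Recasts a landscape as a graph: every cell is a node, and each
#' ordered Moore-neighbour pair `(l, k)` with a positive spread
#' probability contributes a directed edge `l -> k` whose weight is the
#' probability that fire propagates from `l` into `k` (simple model:
#' `1 - s2(k)`; full model: [transition_prob()]).  Non-flammable cells
#' are isolated -- they carry no edges in either direction.  Self loops
#' never occur, and every node has at most 8 outgoing edges.
#'
#' @param grid A [landscape_grid] of either model kind.
#' @param params [ca_params()] for full-model grids.
#' @return A `fire_network`: list with `n_nodes`, `adjacency` (sparse
#'   `dgCMatrix`, entry `[l, k]` = weight of edge `l -> k`), `grid_dim`,
#'   and `lambda_max` (cache, filled on first eigencentrality
#'   computation).
#' @examples
#' f <- artificial_forest(10, seed = 1)
#' net <- build_network(f)
#' net
#' @export
build_network <- function(grid, params = NULL) {
  off <- moore_offsets()
  nr <- grid$n_rows; nc <- grid$n_cols
  N <- nr * nc
  flam <- flammable_cells(grid)
  dir_probs <- direction_probs(grid, params)

  rows_all <- matrix(seq_len(nr), nr, nc)
  cols_all <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (d in seq_len(8)) {
    dr <- off[d, "dr"]; dc <- off[d, "dc"]
    # source (from) cell of the fire arriving at (r, c) from offset d
    sr <- rows_all + dr; sc <- cols_all + dc
    if (grid$boundary == "periodic") {
      sr <- ((sr - 1L) %% nr) + 1L
      sc <- ((sc - 1L) %% nc) + 1L
      valid <- matrix(TRUE, nr, nc)
    } else {
      valid <- sr >= 1L & sr <= nr & sc >= 1L & sc <= nc
      sr[!valid] <- 1L; sc[!valid] <- 1L
    }
    p <- dir_probs[[d]]
    src_flam <- matrix(flam[cbind(as.vector(sr), as.vector(sc))], nr, nc)
    keep <- valid & p > 0 & flam & src_flam
    if (any(keep)) {
      from <- c(from, (sr[keep] - 1L) * nc + sc[keep])
      to <- c(to, (rows_all[keep] - 1L) * nc + cols_all[keep])
      w <- c(w, p[keep])
    }
  }
  structure(list(n_nodes = N,
                 adjacency = Matrix::sparseMatrix(
                   i = from, j = to, x = w, dims = c(N, N)),
                 grid_dim = c(nr, nc),
                 lambda_max = NA_real_),
            class = "fire_network")
}

#' @export
print.fire_network <- function(x, ...) {
  nnz <- Matrix::nnzero(x$adjacency)
  cat(sprintf("fire_network: %d nodes (%d x %d lattice), %d directed edges\n",
              x$n_nodes, x$grid_dim[1], x$grid_dim[2], nnz))
  if (nnz > 0)
    cat(sprintf("  weight range: [%.4g, %.4g]\n",
                min(x$adjacency@x), max(x$adjacency@x)))
  invisible(x)
}

#' Edge weight to path distance
#'
#' Shortest-path centralities need distances that shrink as spread
#' probabilities grow.  The default transform is the literal reciprocal
#' `1 / p`; `-log(p)` is offered as an alternative under which path
#' length corresponds to the log-probability of the whole chain of
#' crossings.  Both are monotone decreasing, so on lattices of uniform
#' structure they induce the same shortest-path orderings.
#'
#' @param weight Edge probability(ies) in `(0, 1]`.
#' @param transform `"inverse"` (default) or `"neglog"`.
#' @return Distances; `weight = 1` maps to 1 (inverse) or 0 (neglog).
#' @export
edge_distance <- function(weight, transform = c("inverse", "neglog")) {
  transform <- match.arg(transform)
  if (!is.numeric(weight) || any(!is.finite(weight)) ||
      any(weight <= 0 | weight > 1))
    stop("`weight` must be in (0, 1]", call. = FALSE)
  if (transform == "inverse") 1 / weight else -log(weight)
}

as_igraph <- function(network, transform = "inverse") {
  g <- igraph::graph_from_adjacency_matrix(network$adjacency,
                                           mode = "directed",
                                           weighted = TRUE)
  igraph::E(g)$distance <- edge_distance(igraph::E(g)$weight, transform)
  g
}

#' Node centralities on the fire-spread network
#'
#' Scores every node of the network by one of five measures, all taken
#' in the flow direction (an edge `l -> k` carries fire *into* `k`):
#'
#' * `"betweenness"` -- fraction of weighted shortest paths (distances
#'   from [edge_distance()]) passing through the node, with exact
#'   geodesic-multiplicity tie handling.
#' * `"closeness"` -- reciprocal of the summed geodesic out-distances;
#'   on graphs with unreachable pairs the sum runs over reached targets
#'   only and is scaled by `(N - 1) / reached` before inverting, so
#'   poorly connected nodes are penalised.
#' * `"eigen"` -- principal eigenvector of the in-weight structure
#'   (Arnoldi/ARPACK iteration on the sparse adjacency), normalised to
#'   unit sum.
#' * `"bonacich"` -- power centrality `x = (I - (beta / lambda_max)
#'   A^T)^(-1) e` via a sparse direct solve, `e` the all-ones vector and
#'   `lambda_max` the spectral radius of the adjacency.  As `beta -> 0`
#'   the induced ranking approaches weighted in-degree; as `beta -> 1`
#'   it approaches eigencentrality.
#' * `"degree"` -- weighted in-degree (column sums of the adjacency).
#'
#' @param network A [build_network()] result.
#' @param measure One of `"betweenness"`, `"closeness"`, `"eigen"`,
#'   `"bonacich"`, `"degree"`.
#' @param beta Attenuation in `[0, 1)` (Bonacich only).
#' @param transform Distance transform for the path-based measures; see
#'   [edge_distance()].
#' @param tol,max_iter Convergence control for the eigenvector solve.
#' @return A `centrality_scores` object: numeric vector of length
#'   `n_nodes` with attributes `measure` and (for Bonacich) `beta`.
#' @export
centrality <- function(network,
                       measure = c("betweenness", "closeness", "eigen",
                                   "bonacich", "degree"),
                       beta = 0.5, transform = "inverse",
                       tol = 1e-8, max_iter = NULL) {
  measure <- match.arg(measure)
  if (!inherits(network, "fire_network"))
    stop("expected a `fire_network`; see `build_network()`", call. = FALSE)
  N <- network$n_nodes
  scores <- switch(
    measure,
    betweenness = {
      if (N < 3) stop("betweenness needs at least 3 nodes", call. = FALSE)
      g <- as_igraph(network, transform)
      as.numeric(igraph::betweenness(g, directed = TRUE,
                                     weights = igraph::E(g)$distance))
    },
    closeness = closeness_scores(network, transform),
    eigen = eigen_scores(network, tol, max_iter)$vector,
    bonacich = bonacich_scores(network, beta, tol, max_iter),
    degree = as.numeric(Matrix::colSums(network$adjacency)))
  structure(scores, class = "centrality_scores", measure = measure,
            beta = if (measure == "bonacich") beta else NA_real_)
}

closeness_scores <- function(network, transform = "inverse") {
  g <- as_igraph(network, transform)
  D <- igraph::distances(g, mode = "out",
                         weights = igraph::E(g)$distance)
  diag(D) <- Inf
  N <- network$n_nodes
  apply(D, 1, function(d) {
    reached <- sum(is.finite(d))
    if (reached == 0) return(0)
    (reached / (N - 1)) / sum(d[is.finite(d)])
  })
}

# principal eigenpair of the in-weight structure via ARPACK (Arnoldi
# iteration); scales to large sparse asymmetric adjacencies where naive
# power iteration stalls on near-degenerate spectra
eigen_scores <- function(network, tol = 1e-8, max_iter = NULL) {
  A <- network$adjacency
  N <- network$n_nodes
  if (N == 0) stop("empty network", call. = FALSE)
  if (Matrix::nnzero(A) == 0)
    return(list(vector = rep(1 / N, N), lambda = 0))
  g <- igraph::graph_from_adjacency_matrix(A, mode = "directed",
                                           weighted = TRUE)
  res <- tryCatch(
    igraph::eigen_centrality(
      g, directed = TRUE, weights = igraph::E(g)$weight,
      options = list(tol = tol,
                     maxiter = max_iter %||% max(3000L, 10L * N))),
    error = function(e)
      stop("eigencentrality (Arnoldi) did not converge: ",
           conditionMessage(e), call. = FALSE))
  v <- abs(res$vector)
  list(vector = v / sum(v), lambda = res$value)
}

bonacich_scores <- function(network, beta, tol = 1e-8, max_iter = NULL) {
  if (!is.numeric(beta) || length(beta) != 1L || beta < 0)
    stop("`beta` must be a single number in [0, 1)", call. = FALSE)
  if (beta >= 1)
    stop("`beta` >= 1 makes the Bonacich system singular or divergent",
         call. = FALSE)
  N <- network$n_nodes
  if (beta == 0) return(rep(1, N))
  lam <- spectral_radius(network, tol, max_iter)
  if (lam <= 0) return(rep(1, N))
  M <- Matrix::Diagonal(N) - (beta / lam) * Matrix::t(network$adjacency)
  as.numeric(Matrix::solve(M, rep(1, N)))
}

#' Spectral radius of the adjacency matrix
#'
#' Largest eigenvalue of the (non-negative) adjacency, computed by the
#' same Arnoldi iteration as eigencentrality.
#'
#' @param network A [build_network()] result.
#' @param tol,max_iter Convergence control.
#' @export
spectral_radius <- function(network, tol = 1e-8, max_iter = NULL) {
  if (!is.na(network$lambda_max)) return(network$lambda_max)
  eigen_scores(network, tol, max_iter)$lambda
}

#' @export
print.centrality_scores <- function(x, ...) {
  m <- attr(x, "measure")
  cat(sprintf("centrality_scores: %s%s over %d nodes\n", m,
              if (m == "bonacich") sprintf(" (beta = %g)", attr(x, "beta"))
              else "", length(x)))
  print(summary(as.numeric(x)))
  invisible(x)
}

#' @export
as.data.frame.centrality_scores <- function(x, row.names = NULL,
                                            optional = FALSE, grid = NULL,
                                            ...) {
  n <- length(x)
  out <- data.frame(node = seq_len(n), score = as.numeric(x))
  if (!is.null(grid)) {
    rc <- node_coords(out$node, grid)
    out$row <- rc[, "row"]
    out$col <- rc[, "col"]
    out <- out[, c("node", "row", "col", "score")]
  }
  out
}

#' Rank nodes by score, best first
#'
#' Descending score with ties broken by ascending node index, so a
#' ranking is always deterministic.
#'
#' @param scores A numeric vector or `centrality_scores`.
#' @return Integer vector of node indices, highest score first.
#' @export
rank_nodes <- function(scores) {
  order(-as.numeric(scores), seq_along(scores))
}

#' Export the adjacency in Matrix Market format
#'
#' @param network A [build_network()] result.
#' @param path Output `.mtx` path.
#' @export
write_network_mtx <- function(network, path) {
  Matrix::writeMM(network$adjacency, path)
  invisible(path)
}
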