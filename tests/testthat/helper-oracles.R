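# Independent reference implementations used as oracles: a dense
# Floyd-Warshall shortest-path/geodesic-counting routine, dense
# eigen/linear-algebra solvers, and a plain loop-based CA.  These share
# no code with the package's own paths.

# wrap a dense weight matrix as a fire_network
make_network <- function(W) {
  structure(list(n_nodes = nrow(W),
                 adjacency = methods::as(Matrix::Matrix(W, sparse = TRUE),
                                         "generalMatrix"),
                 grid_dim = c(1L, nrow(W)),
                 lambda_max = NA_real_),
            class = "fire_network")
}

# random weighted digraph; weights from {0.25, 0.5, 1} so inverse
# distances are exact dyadic rationals and geodesic ties are genuine
rand_weight_digraph <- function(N, p_edge = 0.25, seed = 1) {
  set.seed(seed)
  W <- matrix(0, N, N)
  edges <- matrix(runif(N * N) < p_edge, N, N)
  diag(edges) <- FALSE
  W[edges] <- sample(c(0.25, 0.5, 1), sum(edges), replace = TRUE)
  W
}

# all-pairs shortest distances and geodesic counts on 1/w distances
oracle_paths <- function(W) {
  N <- nrow(W)
  L <- matrix(Inf, N, N)
  L[W > 0] <- 1 / W[W > 0]
  diag(L) <- Inf
  D <- L
  diag(D) <- 0
  for (m in seq_len(N)) {
    for (i in seq_len(N)) {
      nd <- D[i, m] + D[m, ]
      upd <- nd < D[i, ]
      D[i, upd] <- nd[upd]
    }
  }
  sigma <- matrix(0, N, N)
  for (l in seq_len(N)) {
    sigma[l, l] <- 1
    for (m in order(D[l, ])) {
      if (m == l || !is.finite(D[l, m])) next
      preds <- which(is.finite(L[, m]) & D[l, ] + L[, m] == D[l, m])
      sigma[l, m] <- sum(sigma[l, preds])
    }
  }
  list(D = D, L = L, sigma = sigma)
}

oracle_betweenness <- function(W) {
  o <- oracle_paths(W)
  N <- nrow(W)
  bc <- numeric(N)
  for (k in seq_len(N)) {
    for (l in seq_len(N)) {
      if (l == k) next
      for (m in seq_len(N)) {
        if (m == k || m == l) next
        if (!is.finite(o$D[l, m]) || o$sigma[l, m] == 0) next
        if (o$D[l, k] + o$D[k, m] == o$D[l, m])
          bc[k] <- bc[k] + o$sigma[l, k] * o$sigma[k, m] / o$sigma[l, m]
      }
    }
  }
  bc
}

oracle_closeness <- function(W) {
  o <- oracle_paths(W)
  N <- nrow(W)
  vapply(seq_len(N), function(k) {
    d <- o$D[k, -k]
    r <- sum(is.finite(d))
    if (r == 0) return(0)
    (r / (N - 1)) / sum(d[is.finite(d)])
  }, numeric(1))
}

oracle_eigencentrality <- function(W) {
  ev <- eigen(t(W))
  i <- which.max(Mod(ev$values))
  v <- abs(Re(ev$vectors[, i]))
  v / sum(v)
}

oracle_bonacich <- function(W, beta) {
  lam <- max(Re(eigen(W, only.values = TRUE)$values))
  solve(diag(nrow(W)) - (beta / lam) * t(W), rep(1, nrow(W)))
}

# plain loop-based simple-model CA (per-neighbour Bernoulli trials),
# independent of the package's vectorised kernel
oracle_simple_ca <- function(emptiness, ign_rc, periodic = TRUE) {
  nr <- nrow(emptiness); nc <- ncol(emptiness)
  s1 <- matrix(0L, nr, nc)
  if (emptiness[ign_rc[1], ign_rc[2]] >= 1) return(0)
  s1[ign_rc[1], ign_rc[2]] <- 1L
  repeat {
    burning <- which(s1 == 1L, arr.ind = TRUE)
    if (nrow(burning) == 0L) break
    nxt <- s1
    nxt[s1 == 1L] <- -1L
    for (b in seq_len(nrow(burning))) {
      for (dr in -1:1) {
        for (dc in -1:1) {
          if (dr == 0L && dc == 0L) next
          r <- burning[b, 1] + dr
          cc <- burning[b, 2] + dc
          if (periodic) {
            r <- (r - 1L) %% nr + 1L
            cc <- (cc - 1L) %% nc + 1L
          } else if (r < 1L || r > nr || cc < 1L || cc > nc) next
          if (s1[r, cc] != 0L || nxt[r, cc] == 1L) next
          if (runif(1) < 1 - emptiness[r, cc]) nxt[r, cc] <- 1L
        }
      }
    }
    s1 <- nxt
  }
  sum(s1 == -1L)
}

# Welch two-sample t statistic and two-sided p value from the textbook
# formulas
oracle_welch <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  t_stat <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t_stat, df = df, p = 2 * pt(-abs(t_stat), df))
}

# uniform-weight periodic lattice (every in-edge weight `w`)
uniform_torus <- function(n, w = 0.5) {
  g <- artificial_forest(n, seed = 1)
  g$emptiness[] <- 1 - w
  g
}

# TRUE if any pair of nodes is adjacent under the given offsets
any_adjacent <- function(nodes, grid, offsets) {
  if (length(nodes) < 2) return(FALSE)
  rc <- node_coords(nodes, grid)
  for (i in seq_along(nodes)) {
    dr <- abs(rc[, "row"] - rc[i, "row"])
    dc <- abs(rc[, "col"] - rc[i, "col"])
    if (grid$boundary == "periodic") {
      dr <- pmin(dr, grid$n_rows - dr)
      dc <- pmin(dc, grid$n_cols - dc)
    }
    hit <- switch(attr(offsets, "kind") %||% "moore",
                  moore = dr <= 1 & dc <= 1,
                  rook = (dr + dc) == 1)
    hit[i] <- FALSE
    if (any(hit)) return(TRUE)
  }
  FALSE
}

moore_adjacent_pair <- function(nodes, grid) {
  any_adjacent(nodes, grid, structure(1, kind = "moore"))
}

rook_adjacent_pair <- function(nodes, grid) {
  any_adjacent(nodes, grid, structure(1, kind = "rook"))
}
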