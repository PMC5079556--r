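#' @title Lattice landscape grids
#'
#' @description A `landscape_grid` tessellates the terrain into square
#' cells; each cell is a node of the fire-spread network.  Two model
#' kinds are supported:
#'
#' * `"simple"` -- a homogeneous flat landscape where the only fuel state
#'   is the *emptiness* `s2` of each cell, a real in `[0, 1]` (1 = empty
#'   or already burned, 0 = very dense vegetation).  Fire spreads into a
#'   cell with probability `1 - s2`.
#' * `"full"` -- a heterogeneous landscape carrying per-cell vegetation
#'   *type* and *density* effect values (from the [ca_params()] tables),
#'   elevation in meters, and a flammability flag.
#'
#' Cells are addressed by `(row, col)` with row 1 at the grid's north
#' edge (raster order), or by the row-major node index
#' `k = (row - 1) * n_cols + col` (1-based); see [node_index()].
#'
#' @name landscape_grid
NULL

new_landscape <- function(model, n_rows, n_cols, boundary, cell_side,
                          layers) {
  grid <- c(
    list(model = model, n_rows = as.integer(n_rows),
         n_cols = as.integer(n_cols), boundary = boundary,
         cell_side = cell_side,
         burn_state = matrix(0L, n_rows, n_cols)),
    layers)
  class(grid) <- "landscape_grid"
  grid
}

#' Generate a random artificial forest
#'
#' Builds the synthetic study landscape: an `n` x `n` torus (periodic
#' boundaries) of a single vegetation type on flat terrain, where each
#' cell's emptiness `s2` is drawn independently from Uniform(0, 1).
#' Every cell starts susceptible (`burn_state = 0`).
#'
#' @param n Grid side (at least 3); the landscape has `n^2` cells.
#' @param seed Optional integer seed; the same seed reproduces the same
#'   forest bit for bit.
#' @return A simple-model [landscape_grid].
#' @examples
#' f <- artificial_forest(50, seed = 1)
#' range(f$emptiness)   # strictly inside (0, 1)
#' @export
artificial_forest <- function(n, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n != round(n) || n < 3)
    stop("`n` must be a single integer >= 3", call. = FALSE)
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)
  emptiness <- matrix(stats::runif(n * n), n, n, byrow = TRUE)
  new_landscape("simple", n, n, boundary = "periodic", cell_side = NA_real_,
                layers = list(emptiness = emptiness))
}

#' Generate a synthetic heterogeneous landscape
#'
#' A full-model counterpart of [artificial_forest()] for exercising the
#' heterogeneous spread kernel without external GIS data: vegetation
#' type and density categories are drawn per cell from fixed mixing
#' proportions, elevation is a smooth random surface (a sum of sinusoidal
#' ridges), and an optional fraction of cells is left bare (non-fuel).
#' The result uses absorbing boundaries, as a real landscape would.
#'
#' The default mix (20 % agricultural, 40 % other woodland, 40 % pine;
#' equal thirds of sparse/moderate/dense) is a plausible Mediterranean
#' island composition; the relief amplitude of 60 m over 10 m cells
#' gives slope angles up to roughly 30 degrees.
#'
#' @param n Grid side (>= 3).
#' @param seed Optional integer seed.
#' @param params [ca_params()] supplying the effect tables and cell side.
#' @param type_mix,density_mix Named probability vectors over the
#'   categories of the corresponding effect table.
#' @param relief Peak-to-trough elevation range in meters.
#' @param p_bare Probability that a cell carries no fuel at all.
#' @return A full-model [landscape_grid] retaining the category labels
#'   (`type_cat`, `density_cat`) alongside the numeric effect layers.
#' @export
synthetic_landscape <- function(n, seed = NULL, params = ca_params(),
                                type_mix = c(agricultural = 0.2,
                                             other = 0.4, pine = 0.4),
                                density_mix = c(sparse = 1, moderate = 1,
                                                dense = 1) / 3,
                                relief = 60,
                                p_bare = 0.05) {
  if (!is.numeric(n) || length(n) != 1L || n != round(n) || n < 3)
    stop("`n` must be a single integer >= 3", call. = FALSE)
  stopifnot_params(params)
  if (!all(names(type_mix) %in% names(params$type_effects)))
    stop("`type_mix` names must match the type-effect table", call. = FALSE)
  if (!all(names(density_mix) %in% names(params$density_effects)))
    stop("`density_mix` names must match the density-effect table",
         call. = FALSE)
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)
  N <- n * n
  type_cat <- matrix(sample(names(type_mix), N, replace = TRUE,
                            prob = type_mix), n, n, byrow = TRUE)
  density_cat <- matrix(sample(names(density_mix), N, replace = TRUE,
                               prob = density_mix), n, n, byrow = TRUE)
  flammable <- matrix(stats::runif(N) >= p_bare, n, n, byrow = TRUE)

  # smooth surface: a few random sinusoidal ridges, rescaled to `relief`
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  elev <- matrix(0, n, n)
  for (i in 1:3) {
    wl <- stats::runif(1, n / 3, n)          # wavelength in cells
    th <- stats::runif(1, 0, 2 * pi)         # ridge orientation
    ph <- stats::runif(1, 0, 2 * pi)
    elev <- elev + sin(2 * pi * (rows * cos(th) + cols * sin(th)) / wl + ph)
  }
  if (diff(range(elev)) > 0)
    elev <- (elev - min(elev)) / diff(range(elev)) * relief

  grid <- new_landscape(
    "full", n, n, boundary = "absorbing", cell_side = params$cell_side,
    layers = list(
      type_effect = matrix(params$type_effects[type_cat], n, n),
      density_effect = matrix(params$density_effects[density_cat], n, n),
      elevation = elev,
      flammable = flammable,
      type_cat = type_cat,
      density_cat = density_cat))
  grid
}

#' Node index arithmetic
#'
#' Cells and network nodes share a 1-based row-major index,
#' `k = (row - 1) * n_cols + col`, a bijection with `(row, col)`.
#'
#' @param row,col Cell coordinates (1-based; row 1 is the north edge).
#' @param k Node index in `1..n_rows*n_cols`.
#' @param grid A [landscape_grid] (only its dimensions are used).
#' @return `node_index()` the integer index; `node_coords()` a two-column
#'   matrix of `(row, col)`.
#' @export
node_index <- function(row, col, grid) {
  if (any(row < 1 | row > grid$n_rows | col < 1 | col > grid$n_cols))
    stop("cell coordinates out of range", call. = FALSE)
  as.integer((row - 1L) * grid$n_cols + col)
}

#' @rdname node_index
#' @export
node_coords <- function(k, grid) {
  if (any(k < 1 | k > grid$n_rows * grid$n_cols))
    stop("node index out of range", call. = FALSE)
  k <- as.integer(k)
  cbind(row = (k - 1L) %/% grid$n_cols + 1L,
        col = (k - 1L) %% grid$n_cols + 1L)
}

#' Which cells carry fuel?
#'
#' In the simple model a cell is flammable when its emptiness is below 1
#' and it is not burned; in the full model the explicit flammability
#' flag is used.  Returns a logical matrix.
#'
#' @param grid A [landscape_grid].
#' @export
flammable_cells <- function(grid) {
  if (grid$model == "simple") grid$emptiness < 1 else grid$flammable
}

n_vegetation <- function(grid) sum(flammable_cells(grid))

#' @export
print.landscape_grid <- function(x, ...) {
  cat(sprintf("landscape_grid: %d x %d cells, %s model, %s boundaries\n",
              x$n_rows, x$n_cols, x$model, x$boundary))
  if (!is.na(x$cell_side))
    cat(sprintf("  cell side: %g m\n", x$cell_side))
  nf <- n_vegetation(x)
  cat(sprintf("  flammable cells: %d of %d (%.1f%%)\n",
              nf, x$n_rows * x$n_cols, 100 * nf / (x$n_rows * x$n_cols)))
  st <- table(factor(x$burn_state, levels = c(-1, 0, 1),
                     labels = c("burned", "susceptible", "burning")))
  cat("  burn states:", paste(sprintf("%s=%d", names(st), st),
                              collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.landscape_grid <- function(object, ...) {
  print(object)
  if (object$model == "simple") {
    cat("  emptiness: ")
    print(stats::quantile(object$emptiness))
  } else {
    cat("  elevation range:",
        paste(signif(range(object$elevation), 4), collapse = " - "), "m\n")
    if (!is.null(object$type_cat)) {
      cat("  type mix:    ")
      print(round(prop.table(table(object$type_cat)), 3))
      cat("  density mix: ")
      print(round(prop.table(table(object$density_cat)), 3))
    }
  }
  invisible(object)
}
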