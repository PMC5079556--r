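#' @title Stochastic fire-spread kernels
#' @description Cell-to-cell ignition probabilities for the two model
#'   kinds, and the synchronous cellular-automaton update they drive.
#'   Fire states per cell are `s1 = 0` (susceptible), `1` (burning),
#'   `-1` (burned); a burning cell burns down in exactly one step.
#' @name spread-kernels
NULL

# Moore offsets, row-major order; first 4 are diagonal
moore_offsets <- function() {
  cbind(dr = c(-1L, -1L, 1L, 1L, -1L, 0L, 0L, 1L),
        dc = c(-1L, 1L, -1L, 1L, 0L, -1L, 1L, 0L),
        diagonal = c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L))
}

# value of the neighbour at offset (dr, dc) from each cell; `fill` pads
# outside the grid under absorbing boundaries
shift_layer <- function(m, dr, dc, boundary, fill) {
  nr <- nrow(m); nc <- ncol(m)
  if (boundary == "periodic") {
    rows <- ((seq_len(nr) - 1L + dr) %% nr) + 1L
    cols <- ((seq_len(nc) - 1L + dc) %% nc) + 1L
    m[rows, cols, drop = FALSE]
  } else {
    out <- matrix(fill, nr, nc)
    rs <- seq_len(nr) + dr
    cs <- seq_len(nc) + dc
    ok_r <- rs >= 1L & rs <= nr
    ok_c <- cs >= 1L & cs <= nc
    out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c], drop = FALSE]
    out
  }
}

#' Ignition probability in the simple model
#'
#' In the homogeneous artificial forest the probability that fire
#' propagates from a burning neighbour into a cell equals `1 - s2`,
#' where `s2` is the cell's emptiness (1 = empty or burned, 0 = very
#' dense vegetation).
#'
#' @param emptiness Emptiness value(s) `s2` in `[0, 1]`; vectorised.
#' @return Probabilities `1 - emptiness`.
#' @examples
#' simple_spread_prob(c(0, 0.25, 1))   # 1.00 0.75 0.00
#' @export
simple_spread_prob <- function(emptiness) {
  if (!is.numeric(emptiness) || any(!is.finite(emptiness)) ||
      any(emptiness < 0 | emptiness > 1))
    stop("`emptiness` must be numeric in [0, 1]", call. = FALSE)
  1 - emptiness
}

#' Slope angle between neighbouring cells
#'
#' The angle whose tangent is the elevation difference over the
#' horizontal separation: `cell_side` for the four orthogonally adjacent
#' neighbours, `cell_side * sqrt(2)` for the four diagonal ones.  The
#' sign convention follows the spread direction: positive when the
#' burning (source) cell sits above the receiving cell.
#'
#' @param elev_from Elevation of the burning source cell (m).
#' @param elev_to Elevation of the receiving cell (m).
#' @param cell_side Cell side length in meters.
#' @param kind `"adjacent"` (orthogonal) or `"diagonal"`.
#' @return Angle in radians; vectorised over elevations.
#' @export
slope_angle <- function(elev_from, elev_to, cell_side,
                        kind = c("adjacent", "diagonal")) {
  kind <- match.arg(kind)
  if (!is.numeric(cell_side) || length(cell_side) != 1L || cell_side <= 0)
    stop("`cell_side` must be a single positive length", call. = FALSE)
  denom <- if (kind == "diagonal") cell_side * sqrt(2) else cell_side
  atan((elev_from - elev_to) / denom)
}

#' Exponential slope gain
#'
#' Multiplicative effect of terrain slope on the spread probability,
#' `exp(a * theta_s)`; exceeds 1 for positive slope angles (the overall
#' transition probability is clamped to `[0, 1]` downstream).
#'
#' @param theta_s Slope angle(s) in radians (see [slope_angle()]).
#' @param a Positive slope coefficient.
#' @export
slope_gain <- function(theta_s, a) {
  if (!is.numeric(a) || length(a) != 1L || a <= 0)
    stop("`a` must be a single positive number", call. = FALSE)
  exp(a * theta_s)
}

#' Full-model transition probability
#'
#' Probability that fire propagates from a burning cell to a
#' neighbouring flammable cell under the heterogeneous model:
#' `p0 * (1 + s2) * (1 + s3) * exp(a * theta_s)`, where `s2` and `s3`
#' are the receiving cell's vegetation-type and density effects and
#' `theta_s` the slope angle of the crossing.  The product is clamped
#' to `[0, 1]`; a non-flammable receiving cell has probability 0.
#'
#' @param type_effect,density_effect Receiving cell's effect values
#'   (from the [ca_params()] tables).
#' @param params A [ca_params()] object.
#' @param elev_from,elev_to Elevations of the source and receiving cell
#'   in meters (default flat).
#' @param kind Neighbour geometry, `"adjacent"` or `"diagonal"`.
#' @param flammable Logical; `FALSE` forces probability 0.
#' @param wind_gain Optional extra multiplicative factor (default 1), a
#'   hook for a wind model; applied before clamping.
#' @return Probabilities in `[0, 1]`, vectorised over cell inputs.
#' @examples
#' transition_prob(0, 0, ca_params())            # 0.58
#' transition_prob(-0.3, -0.4, ca_params())      # 0.58 * 0.7 * 0.6
#' transition_prob(0.4, 0.3, ca_params())        # clamped to 1
#' @export
transition_prob <- function(type_effect, density_effect, params,
                            elev_from = 0, elev_to = 0,
                            kind = c("adjacent", "diagonal"),
                            flammable = TRUE, wind_gain = 1) {
  stopifnot_params(params)
  kind <- match.arg(kind)
  if (any(is.na(type_effect) & flammable) ||
      any(is.na(density_effect) & flammable))
    stop("full-model states (type/density effects) must be populated ",
         "for flammable cells", call. = FALSE)
  theta <- slope_angle(elev_from, elev_to, params$cell_side, kind)
  p <- params$p0 * (1 + type_effect) * (1 + density_effect) *
    slope_gain(theta, params$a) * wind_gain
  p <- pmin(pmax(p, 0), 1)
  p[!flammable] <- 0
  p[is.na(p)] <- 0
  p
}

# Per-direction ignition-probability layers: dir_probs[[d]][r, c] is the
# probability that a burning neighbour at Moore offset d ignites cell
# (r, c).  Receiving cells that are not flammable get 0.
direction_probs <- function(grid, params = NULL, wind_gain = rep(1, 8)) {
  off <- moore_offsets()
  flam <- flammable_cells(grid)
  if (grid$model == "simple") {
    base <- simple_spread_prob(grid$emptiness)
    base[!flam] <- 0
    return(lapply(seq_len(8), function(d) base * wind_gain[d]))
  }
  if (is.null(params)) params <- ca_params()
  stopifnot_params(params)
  cs <- if (is.na(grid$cell_side)) params$cell_side else grid$cell_side
  lapply(seq_len(8), function(d) {
    # elevation of the neighbour the fire comes from, per receiving cell
    elev_from <- shift_layer(grid$elevation, off[d, "dr"], off[d, "dc"],
                             grid$boundary, fill = NA_real_)
    kind <- if (off[d, "diagonal"] == 1L) "diagonal" else "adjacent"
    te <- grid$type_effect; de <- grid$density_effect
    te[!flam] <- 0; de[!flam] <- 0          # placeholder, zeroed below
    theta <- atan((elev_from - grid$elevation) /
                    (cs * if (kind == "diagonal") sqrt(2) else 1))
    p <- params$p0 * (1 + te) * (1 + de) * exp(params$a * theta) *
      wind_gain[d]
    p <- pmin(pmax(p, 0), 1)
    p[!flam] <- 0
    p[is.na(p)] <- 0                        # off-grid source under absorbing
    p
  })
}

#' One synchronous CA step
#'
#' Advances the fire by one time step, all cells updated simultaneously
#' from the time-`t` states: every burning cell becomes burned; every
#' susceptible flammable cell with at least one burning Moore neighbour
#' ignites with probability `1 - prod(1 - p_l)` over its burning
#' neighbours `l` -- one independent Bernoulli trial per burning
#' neighbour.
#'
#' This is the inner kernel of [run_fire()]; it is exposed for testing
#' and for custom simulation loops.  Ignition-probability layers can be
#' precomputed once with the internal cache and reused across steps.
#'
#' @param grid A [landscape_grid] with some `burn_state` set.
#' @param params [ca_params()] for full-model grids (ignored for simple).
#' @param dir_probs Optional precomputed per-direction probability
#'   layers (internal use).
#' @return The grid one step later.
#' @export
spread_step <- function(grid, params = NULL, dir_probs = NULL) {
  if (is.null(dir_probs)) dir_probs <- direction_probs(grid, params)
  off <- moore_offsets()
  burning <- grid$burn_state == 1L
  s1 <- grid$burn_state
  s1[burning] <- -1L
  if (any(burning)) {
    noign <- matrix(1, grid$n_rows, grid$n_cols)
    for (d in seq_len(8)) {
      nb <- shift_layer(burning, off[d, "dr"], off[d, "dc"],
                        grid$boundary, fill = FALSE)
      if (any(nb)) noign[nb] <- noign[nb] * (1 - dir_probs[[d]][nb])
    }
    ign_p <- 1 - noign
    # one uniform per cell each step: keeps runs with common seeds
    # aligned across nested break plans (common random numbers)
    u <- matrix(stats::runif(grid$n_rows * grid$n_cols),
                grid$n_rows, grid$n_cols)
    new_fire <- grid$burn_state == 0L & flammable_cells(grid) &
      u < ign_p
    s1[new_fire] <- 1L
  }
  grid$burn_state <- s1
  grid
}

#' Run a fire to extinction
#'
#' Ignites one cell and iterates [spread_step()] until no cell is
#' burning.  A run on an `N`-cell grid terminates in at most `N` steps
#' (each step either ignites a new cell or ends the fire).
#'
#' @param grid A [landscape_grid]; its `burn_state` should be all
#'   susceptible.
#' @param ignition Node index (see [node_index()]) or `(row, col)` pair
#'   of the ignition cell; `"center"` picks the central cell.
#' @param seed Optional integer seed for the run.
#' @param params [ca_params()] for full-model grids.
#' @return A `fire_sim` object: `burned_mask` (logical matrix),
#'   `n_burned`, `n_steps`, `ignition` (node index), `seed`.
#'   A non-flammable ignition cell yields `n_burned = 0`.
#' @examples
#' f <- artificial_forest(25, seed = 7)
#' run_fire(f, "center", seed = 1)
#' @export
run_fire <- function(grid, ignition = "center", seed = NULL,
                     params = NULL) {
  ign <- resolve_ignition(grid, ignition)
  if (!is.null(seed)) set.seed(seed)
  rc <- node_coords(ign, grid)
  if (!flammable_cells(grid)[rc]) {
    return(new_fire_sim(matrix(FALSE, grid$n_rows, grid$n_cols),
                        0L, ign, seed))
  }
  dir_probs <- direction_probs(grid, params)
  grid$burn_state[rc] <- 1L
  n_steps <- 0L
  while (any(grid$burn_state == 1L)) {
    grid <- spread_step(grid, params, dir_probs)
    n_steps <- n_steps + 1L
  }
  new_fire_sim(grid$burn_state == -1L, n_steps, ign, seed)
}

resolve_ignition <- function(grid, ignition) {
  if (identical(ignition, "center"))
    return(node_index((grid$n_rows + 1L) %/% 2L,
                      (grid$n_cols + 1L) %/% 2L, grid))
  if (length(ignition) == 2L)
    return(node_index(ignition[1], ignition[2], grid))
  if (length(ignition) == 1L && is.numeric(ignition)) {
    if (ignition < 1 || ignition > grid$n_rows * grid$n_cols)
      stop("ignition node index out of bounds", call. = FALSE)
    return(as.integer(ignition))
  }
  stop("`ignition` must be \"center\", a node index, or (row, col)",
       call. = FALSE)
}

new_fire_sim <- function(burned_mask, n_steps, ignition, seed) {
  structure(list(burned_mask = burned_mask,
                 n_burned = sum(burned_mask),
                 n_steps = as.integer(n_steps),
                 ignition = as.integer(ignition),
                 seed = if (is.null(seed)) NA_integer_ else
                   as.integer(seed)),
            class = "fire_sim")
}

#' @export
print.fire_sim <- function(x, ...) {
  N <- length(x$burned_mask)
  cat(sprintf(
    "fire_sim: %d of %d cells burned (%.1f%%) in %d steps (ignition %d%s)\n",
    x$n_burned, N, 100 * x$n_burned / N, x$n_steps, x$ignition,
    if (is.na(x$seed)) "" else sprintf(", seed %d", x$seed)))
  invisible(x)
}

#' @export
as.data.frame.fire_sim <- function(x, row.names = NULL, optional = FALSE,
                                   ...) {
  data.frame(ignition = x$ignition, seed = x$seed, n_burned = x$n_burned,
             n_steps = x$n_steps)
}
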