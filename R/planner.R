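#' @title Fuel-break placement
#'
#' @description A fuel break removes a cell's vegetation so fire can
#' neither ignite nor cross it.  Plans select `round(d_f * n_v)` cells
#' (`n_v` = number of flammable cells, `d_f` the break density) by
#' sweeping a ranking from best to worst, subject to the constraint
#' that no two breaks may be adjacent -- by default "adjacent" means
#' the four orthogonal neighbours, so diagonal contacts are allowed
#' and break densities up to the checkerboard limit of 1/2 remain
#' feasible; `exclusion = "moore"` extends the constraint to all eight
#' neighbours (packing limit 1/4).  The ranking is computed once on
#' the intact landscape and never revised between removals.
#'
#' @name firebreak_plan
NULL

rook_offsets <- function() {
  cbind(dr = c(-1L, 0L, 0L, 1L), dc = c(0L, -1L, 1L, 0L))
}

neighbor_indices <- function(k, grid,
                             exclusion = c("rook", "moore", "none")) {
  exclusion <- match.arg(exclusion)
  if (exclusion == "none") return(integer(0))
  off <- if (exclusion == "moore") moore_offsets()[, 1:2, drop = FALSE]
         else rook_offsets()
  rc <- node_coords(k, grid)
  rr <- rc[, "row"] + off[, "dr"]
  cc <- rc[, "col"] + off[, "dc"]
  if (grid$boundary == "periodic") {
    rr <- ((rr - 1L) %% grid$n_rows) + 1L
    cc <- ((cc - 1L) %% grid$n_cols) + 1L
  } else {
    ok <- rr >= 1L & rr <= grid$n_rows & cc >= 1L & cc <= grid$n_cols
    rr <- rr[ok]; cc <- cc[ok]
  }
  unique((rr - 1L) * grid$n_cols + cc)
}

new_plan <- function(strategy, removed, d_f_target, n_v, grid,
                     measure = NA_character_, beta = NA_real_,
                     seed = NA_integer_, exclusion = "rook") {
  structure(list(strategy = strategy,
                 removed = as.integer(removed),
                 d_f_target = d_f_target,
                 d_f_achieved = length(removed) / n_v,
                 n_v = as.integer(n_v),
                 grid_dim = c(grid$n_rows, grid$n_cols),
                 measure = measure, beta = beta,
                 seed = if (is.null(seed)) NA_integer_ else
                   as.integer(seed),
                 exclusion = exclusion),
            class = "firebreak_plan")
}

# shared greedy sweep: walk `ranking` (best candidates first), skip
# non-flammable / forbidden / adjacent-to-selected nodes, stop at budget
greedy_select <- function(grid, ranking, d_f, forbidden, exclusion) {
  if (!is.numeric(d_f) || length(d_f) != 1L || d_f < 0 || d_f > 1)
    stop("`d_f` must be a single fraction in [0, 1]", call. = FALSE)
  flam <- as.vector(t(flammable_cells(grid)))   # node-index order
  n_v <- sum(flam)
  budget <- floor(d_f * n_v + 0.5)              # round half away from zero
  if (budget == 0L)
    return(list(removed = integer(0), n_v = n_v))
  eligible <- flam
  eligible[forbidden] <- FALSE
  removed <- integer(0)
  for (k in ranking) {
    if (!eligible[k]) next
    removed <- c(removed, k)
    if (length(removed) >= budget) break
    eligible[k] <- FALSE
    eligible[neighbor_indices(k, grid, exclusion)] <- FALSE
  }
  list(removed = removed, n_v = n_v)
}

#' Place fuel breaks by centrality ranking
#'
#' Sweeps the nodes in descending centrality order (ties broken by
#' ascending node index) and greedily selects breaks under the
#' no-adjacent-removal constraint until `round(d_f * n_v)` cells are
#' chosen or the candidate list is exhausted; a shortfall is reported
#' through `d_f_achieved`, never an error.
#'
#' @param grid A [landscape_grid].
#' @param scores A [centrality()] result (or any per-node numeric
#'   vector covering all nodes).
#' @param d_f Target break density: fraction of flammable cells in
#'   `[0, 1]`.
#' @param forbidden Node indices never to remove (e.g. a planned
#'   ignition cell).
#' @param exclusion Adjacency notion for the constraint: `"rook"`
#'   (4 orthogonal neighbours, default) or `"moore"` (all 8).
#' @return A `firebreak_plan`.
#' @export
place_by_centrality <- function(grid, scores, d_f, forbidden = integer(0),
                                exclusion = c("rook", "moore", "none")) {
  exclusion <- match.arg(exclusion)
  if (length(scores) != grid$n_rows * grid$n_cols)
    stop("`scores` must cover all ", grid$n_rows * grid$n_cols,
         " nodes", call. = FALSE)
  sel <- greedy_select(grid, rank_nodes(scores), d_f, forbidden, exclusion)
  new_plan("centrality", sel$removed, d_f, sel$n_v, grid,
           measure = attr(scores, "measure") %||% NA_character_,
           beta = attr(scores, "beta") %||% NA_real_,
           exclusion = exclusion)
}

#' Place fuel breaks uniformly at random
#'
#' The benchmark strategy: a seeded uniform random scatter of breaks
#' over the flammable nodes.  Random placement is unconstrained by
#' default -- the no-adjacent-removal rule belongs to the *ranked*
#' policies, where it stops the top-ranked cells from coalescing into
#' one clearing; pass `exclusion = "rook"` or `"moore"` to impose it
#' here too.
#'
#' @inheritParams place_by_centrality
#' @param seed Optional integer seed; the same seed reproduces the plan.
#' @export
place_random <- function(grid, d_f, seed = NULL, forbidden = integer(0),
                         exclusion = c("none", "rook", "moore")) {
  exclusion <- match.arg(exclusion)
  if (!is.null(seed)) set.seed(seed)
  flam_nodes <- which(as.vector(t(flammable_cells(grid))))
  ranking <- sample(flam_nodes)
  sel <- greedy_select(grid, ranking, d_f, forbidden, exclusion)
  new_plan("random", sel$removed, d_f, sel$n_v, grid, seed = seed,
           exclusion = exclusion)
}

#' Conventional fuel-reduction ranking
#'
#' The benchmark forestry practice ranks cells by vegetation density
#' and flammability class: dense pine first, then dense other woodland
#' or shrubs, then moderate pine, moderate other, sparse pine, sparse
#' other, and agricultural cells (any density) last.  Ties within a
#' class are broken by ascending node index.
#'
#' @param grid A full-model [landscape_grid] retaining its category
#'   labels (`type_cat`, `density_cat`).
#' @return Integer vector of flammable node indices, highest priority
#'   first -- pass it to [place_breaks()].
#' @export
conventional_ranking <- function(grid) {
  if (grid$model != "full" || is.null(grid$type_cat) ||
      is.null(grid$density_cat))
    stop("conventional ranking needs a full-model grid with vegetation ",
         "category labels", call. = FALSE)
  ty <- as.vector(t(grid$type_cat))
  de <- as.vector(t(grid$density_cat))
  flam <- as.vector(t(flammable_cells(grid)))
  class_of <- function(type, dens) {
    ifelse(type == "agricultural", 7L,
      ifelse(dens == "dense" & type == "pine", 1L,
      ifelse(dens == "dense", 2L,
      ifelse(dens == "moderate" & type == "pine", 3L,
      ifelse(dens == "moderate", 4L,
      ifelse(type == "pine", 5L, 6L))))))
  }
  pr <- class_of(ty, de)
  nodes <- which(flam)
  nodes[order(pr[nodes], nodes)]
}

#' Place fuel breaks along an explicit ranking
#'
#' The generic greedy sweep behind every strategy, exposed so custom
#' orderings (e.g. [conventional_ranking()]) can be planned directly.
#'
#' @inheritParams place_by_centrality
#' @param ranking Integer vector of node indices, best candidate first;
#'   nodes not listed are never selected.
#' @param strategy Label recorded in the plan.
#' @export
place_breaks <- function(grid, ranking, d_f, forbidden = integer(0),
                         exclusion = c("rook", "moore", "none"),
                         strategy = "conventional") {
  exclusion <- match.arg(exclusion)
  sel <- greedy_select(grid, as.integer(ranking), d_f, forbidden,
                       exclusion)
  new_plan(strategy, sel$removed, d_f, sel$n_v, grid,
           exclusion = exclusion)
}

#' Apply a plan to a landscape
#'
#' Clears the vegetation of the plan's cells: in the simple model their
#' emptiness becomes 1, in the full model they are flagged
#' non-flammable.  Burn states are untouched.
#'
#' @param grid The [landscape_grid] the plan was made for.
#' @param plan A `firebreak_plan`.
#' @return The treated grid.
#' @export
apply_breaks <- function(grid, plan) {
  if (!inherits(plan, "firebreak_plan"))
    stop("`plan` must be a firebreak_plan", call. = FALSE)
  if (length(plan$removed) == 0L) return(grid)
  if (any(plan$removed < 1 | plan$removed > grid$n_rows * grid$n_cols))
    stop("plan node index out of range for this grid", call. = FALSE)
  rc <- node_coords(plan$removed, grid)
  if (grid$model == "simple") {
    grid$emptiness[rc] <- 1
  } else {
    grid$flammable[rc] <- FALSE
  }
  grid
}

#' @export
print.firebreak_plan <- function(x, ...) {
  cat(sprintf(
    "firebreak_plan (%s%s): %d breaks, d_f %.4g achieved (%.4g targeted)\n",
    x$strategy,
    if (!is.na(x$measure)) paste0(": ", x$measure,
      if (!is.na(x$beta)) sprintf(", beta=%g", x$beta) else "") else "",
    length(x$removed), x$d_f_achieved, x$d_f_target))
  cat(sprintf("  constraint: no two breaks %s-adjacent; n_v = %d\n",
              x$exclusion, x$n_v))
  invisible(x)
}

#' Plan serialisation
#'
#' Plans round-trip through JSON (strategy, parameters, node indices,
#' break densities); [plan_mask()] renders a plan as a 0/1 matrix for
#' export with [write_esri_ascii()].
#'
#' @param plan A `firebreak_plan`.
#' @param path File path.
#' @export
write_plan <- function(plan, path) {
  jsonlite::write_json(unclass(plan), path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$removed <- as.integer(x$removed)
  x$n_v <- as.integer(x$n_v)
  x$seed <- if (is.null(x$seed) || is.na(x$seed)) NA_integer_ else
    as.integer(x$seed)
  if (is.null(x$measure)) x$measure <- NA_character_
  if (is.null(x$beta)) x$beta <- NA_real_
  structure(x, class = "firebreak_plan")
}

#' @rdname write_plan
#' @param grid The plan's landscape (for dimensions).
#' @export
plan_mask <- function(plan, grid) {
  m <- matrix(0L, grid$n_rows, grid$n_cols)
  if (length(plan$removed)) m[node_coords(plan$removed, grid)] <- 1L
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
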