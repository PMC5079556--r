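#' Hazard intensity
#'
#' Mean burned fraction over a set of simulations:
#' `R = mean(n_burned / n_v)`, where `n_v` is the number of
#' flammable-vegetation cells of the (untreated) landscape.
#'
#' @param burned_counts Non-negative per-run burned-cell counts.
#' @param n_v Number of flammable cells (> 0).
#' @return The hazard intensity, a fraction in `[0, 1]`.
#' @examples
#' hazard_intensity(c(10, 20, 30), 100)   # 0.2
#' @export
hazard_intensity <- function(burned_counts, n_v) {
  if (length(burned_counts) == 0)
    stop("`burned_counts` must be non-empty", call. = FALSE)
  if (any(burned_counts < 0) || n_v <= 0)
    stop("counts must be non-negative and `n_v` positive", call. = FALSE)
  mean(burned_counts / n_v)
}

#' Strategy specifications for hazard campaigns
#'
#' Small constructors describing how a campaign should place its fuel
#' breaks: by a network centrality ranking, uniformly at random, or by
#' the conventional density/flammability sort.
#'
#' @param measure,beta Centrality measure and Bonacich attenuation; see
#'   [centrality()].
#' @param exclusion Per-strategy override of the campaign's adjacency
#'   constraint (`"rook"`, `"moore"` or `"none"`).  `NULL` inherits the
#'   campaign-wide setting; the random benchmark defaults to `"none"`
#'   (an unranked scatter is not subject to the no-adjacent rule).
#' @return A `break_strategy` spec for [hazard_campaign()].
#' @export
strategy_centrality <- function(measure = "bonacich", beta = 0.5,
                                exclusion = NULL) {
  structure(list(type = "centrality", measure = measure, beta = beta,
                 exclusion = exclusion),
            class = "break_strategy")
}

#' @rdname strategy_centrality
#' @export
strategy_random <- function(exclusion = "none") {
  structure(list(type = "random", exclusion = exclusion),
            class = "break_strategy")
}

#' @rdname strategy_centrality
#' @export
strategy_conventional <- function(exclusion = NULL) {
  structure(list(type = "conventional", exclusion = exclusion),
            class = "break_strategy")
}

# one full greedy pass; prefixes of the returned order are the plans
# for every budget (the sweep never revisits decisions)
greedy_sequence <- function(grid, ranking, forbidden, exclusion) {
  flam <- as.vector(t(flammable_cells(grid)))
  eligible <- flam
  eligible[forbidden] <- FALSE
  removed <- integer(0)
  for (k in ranking) {
    if (!eligible[k]) next
    removed <- c(removed, k)
    eligible[k] <- FALSE
    eligible[neighbor_indices(k, grid, exclusion)] <- FALSE
  }
  removed
}

strategy_rankings <- function(grid, strategies, params, seed) {
  net <- NULL
  scores_cache <- list()
  lapply(strategies, function(st) {
    switch(st$type,
      centrality = {
        key <- paste(st$measure, st$beta %||% "")
        if (is.null(scores_cache[[key]])) {
          if (is.null(net)) net <<- build_network(grid, params)
          scores_cache[[key]] <<- centrality(net, st$measure,
                                             beta = st$beta %||% 0.5)
        }
        rank_nodes(scores_cache[[key]])
      },
      random = {
        set.seed(seed)
        sample(which(as.vector(t(flammable_cells(grid)))))
      },
      conventional = conventional_ranking(grid),
      stop("unknown strategy type: ", st$type, call. = FALSE))
  })
}

#' Run a Monte-Carlo hazard campaign
#'
#' Evaluates one or more fuel-break strategies across a grid of break
#' densities `d_f`, recording the burned fraction of every simulation.
#' Two campaign modes are supported:
#'
#' * `"ensemble"` -- `n_runs` independent landscape realisations (one
#'   fire each, fixed ignition, default the central cell): `landscape`
#'   must be a generator `function(seed)` returning a fresh
#'   [landscape_grid].
#' * `"multi_ignition"` -- one fixed landscape, `n_runs` fires from
#'   ignition cells drawn uniformly among the flammable cells:
#'   `landscape` is the grid itself.
#'
#' Rankings are computed once per landscape on the intact grid; the
#' break sets for increasing `d_f` are nested prefixes of one greedy
#' sweep, and simulation seeds are shared across strategies and break
#' densities (common random numbers), which makes paired strategy
#' comparisons sharp.
#'
#' All randomness derives from `base_seed` (landscape seeds
#' `base_seed + run`, simulation and placement seeds at fixed large
#' offsets); keep `base_seed` below 2^30.
#'
#' @param landscape A generator `function(seed)` (ensemble mode) or a
#'   [landscape_grid] (multi-ignition mode).
#' @param strategies Named list of [strategy_centrality()] /
#'   [strategy_random()] / [strategy_conventional()] specs.
#' @param d_f_grid Increasing vector of break densities in `[0, 1]`.
#' @param n_runs Number of runs (realisations or ignitions).
#' @param mode `"ensemble"` or `"multi_ignition"`.
#' @param ignition Ignition spec for ensemble mode (default central
#'   cell); ignored in multi-ignition mode.
#' @param base_seed Master seed of the campaign.
#' @param params [ca_params()] for full-model landscapes.
#' @param exclusion Adjacency notion of the placement constraint; see
#'   [place_by_centrality()].
#' @return A `hazard_curve` object holding the per-run burned
#'   fractions (`fractions`, an `n_runs` x `length(d_f_grid)` x
#'   `n_strategies` array), per-cell means `mean_R`, 90th percentiles
#'   `p90`, and the campaign metadata.
#' @export
hazard_campaign <- function(landscape, strategies,
                            d_f_grid = seq(0, 0.5, by = 0.02),
                            n_runs = 100,
                            mode = c("ensemble", "multi_ignition"),
                            ignition = "center",
                            base_seed = 1,
                            params = NULL,
                            exclusion = c("rook", "moore", "none")) {
  mode <- match.arg(mode)
  exclusion <- match.arg(exclusion)
  if (is.unsorted(d_f_grid, strictly = TRUE))
    stop("`d_f_grid` must be strictly increasing", call. = FALSE)
  if (is.null(names(strategies)) || any(!nzchar(names(strategies))))
    stop("`strategies` must be a fully named list", call. = FALSE)
  n_st <- length(strategies)
  n_df <- length(d_f_grid)
  fractions <- array(NA_real_,
                     dim = c(n_runs, n_df, n_st),
                     dimnames = list(NULL, NULL, names(strategies)))
  achieved <- array(NA_real_, dim = c(n_runs, n_df, n_st),
                    dimnames = list(NULL, NULL, names(strategies)))
  st_excl <- vapply(strategies, function(st) st$exclusion %||% exclusion,
                    character(1))

  sim_seed <- function(run) base_seed + 500000L + run
  perm_seed <- function(run) base_seed + 900000L + run

  if (mode == "ensemble") {
    if (!is.function(landscape))
      stop("ensemble mode needs a landscape generator `function(seed)`",
           call. = FALSE)
    for (run in seq_len(n_runs)) {
      grid <- landscape(base_seed + run)
      ign <- resolve_ignition(grid, ignition)
      if (!flammable_cells(grid)[node_coords(ign, grid)])
        stop("ignition cell is not flammable in realisation ", run,
             call. = FALSE)
      rankings <- strategy_rankings(grid, strategies, params,
                                    perm_seed(run))
      for (s in seq_len(n_st)) {
        seq_rm <- greedy_sequence(grid, rankings[[s]], ign, st_excl[s])
        n_v <- n_vegetation(grid)
        for (j in seq_len(n_df)) {
          budget <- floor(d_f_grid[j] * n_v + 0.5)
          removed <- seq_rm[seq_len(min(budget, length(seq_rm)))]
          treated <- grid
          if (length(removed)) {
            rc <- node_coords(removed, grid)
            if (grid$model == "simple") treated$emptiness[rc] <- 1
            else treated$flammable[rc] <- FALSE
          }
          sim <- run_fire(treated, ign, seed = sim_seed(run), params)
          fractions[run, j, s] <- sim$n_burned / n_v
          achieved[run, j, s] <- length(removed) / n_v
        }
      }
    }
  } else {
    grid <- landscape
    if (!inherits(grid, "landscape_grid"))
      stop("multi-ignition mode needs a landscape_grid", call. = FALSE)
    flam_nodes <- which(as.vector(t(flammable_cells(grid))))
    if (!length(flam_nodes))
      stop("no flammable ignition available", call. = FALSE)
    set.seed(base_seed)
    ignitions <- sample(flam_nodes, n_runs, replace = TRUE)
    rankings <- strategy_rankings(grid, strategies, params,
                                  perm_seed(0L))
    n_v <- n_vegetation(grid)
    for (s in seq_len(n_st)) {
      seq_rm <- greedy_sequence(grid, rankings[[s]], integer(0),
                                st_excl[s])
      for (j in seq_len(n_df)) {
        budget <- floor(d_f_grid[j] * n_v + 0.5)
        removed <- seq_rm[seq_len(min(budget, length(seq_rm)))]
        treated <- grid
        if (length(removed)) {
          rc <- node_coords(removed, grid)
          if (grid$model == "simple") treated$emptiness[rc] <- 1
          else treated$flammable[rc] <- FALSE
        }
        dir_probs <- direction_probs(treated, params)
        for (run in seq_len(n_runs)) {
          sim <- run_fire_cached(treated, ignitions[run],
                                 seed = sim_seed(run), params, dir_probs)
          fractions[run, j, s] <- sim$n_burned / n_v
          achieved[run, j, s] <- length(removed) / n_v
        }
      }
    }
  }

  structure(list(
    d_f_grid = d_f_grid,
    strategies = names(strategies),
    strategy_specs = strategies,
    fractions = fractions,
    d_f_achieved = apply(achieved, c(2, 3), mean),
    mean_R = apply(fractions, c(2, 3), mean),
    p90 = apply(fractions, c(2, 3), stats::quantile, probs = 0.9,
                names = FALSE),
    n_runs = n_runs, mode = mode, base_seed = base_seed,
    exclusion = exclusion),
    class = "hazard_curve")
}

# run_fire with precomputed direction probabilities (hot loop helper)
run_fire_cached <- function(grid, ignition, seed, params, dir_probs) {
  ign <- resolve_ignition(grid, ignition)
  if (!is.null(seed)) set.seed(seed)
  rc <- node_coords(ign, grid)
  if (!flammable_cells(grid)[rc])
    return(new_fire_sim(matrix(FALSE, grid$n_rows, grid$n_cols), 0L,
                        ign, seed))
  grid$burn_state[rc] <- 1L
  n_steps <- 0L
  while (any(grid$burn_state == 1L)) {
    grid <- spread_step(grid, params, dir_probs)
    n_steps <- n_steps + 1L
  }
  new_fire_sim(grid$burn_state == -1L, n_steps, ign, seed)
}

#' @export
print.hazard_curve <- function(x, ...) {
  cat(sprintf(
    "hazard_curve: %d strategies x %d break densities, %d runs (%s mode)\n",
    length(x$strategies), length(x$d_f_grid), x$n_runs, x$mode))
  tab <- round(t(x$mean_R), 3)
  colnames(tab) <- format(x$d_f_grid, trim = TRUE)
  rownames(tab) <- x$strategies
  keep <- unique(round(seq(1, length(x$d_f_grid), length.out = 8)))
  print(tab[, keep, drop = FALSE])
  invisible(x)
}

#' @export
summary.hazard_curve <- function(object, ...) {
  print(object)
  tr <- vapply(object$strategies, function(s)
    tryCatch(detect_transition(object, s), error = function(e) NA_real_),
    numeric(1))
  cat("detected transitions d_f*:\n")
  print(round(tr, 3))
  invisible(object)
}

#' @export
as.data.frame.hazard_curve <- function(x, row.names = NULL,
                                       optional = FALSE, ...) {
  grid <- expand.grid(d_f = x$d_f_grid, strategy = x$strategies,
                      stringsAsFactors = FALSE)
  data.frame(strategy = grid$strategy, d_f = grid$d_f,
             d_f_achieved = as.vector(x$d_f_achieved),
             mean_R = as.vector(x$mean_R), p90 = as.vector(x$p90),
             n_runs = x$n_runs)
}

#' @export
plot.hazard_curve <- function(x, ..., legend_pos = "topright") {
  graphics::matplot(x$d_f_grid, x$mean_R, type = "b", pch = seq_len(8),
                    lty = 1, xlab = expression(d[f]),
                    ylab = expression(R(d[f])), ...)
  graphics::legend(legend_pos, legend = x$strategies,
                   col = seq_len(ncol(x$mean_R)), pch = seq_len(8),
                   lty = 1, bty = "n")
  invisible(x)
}

#' Welch comparison of two strategies
#'
#' Two-sample t-test (unequal variances) on the per-run burned
#' fractions of two strategies at every break density of a campaign.
#'
#' @param curve A [hazard_campaign()] result.
#' @param a,b Strategy names in `curve$strategies`.
#' @param alpha Significance threshold.
#' @param var_equal Use the pooled-variance test instead of Welch.
#' @return Data frame with one row per `d_f`: the two means, the t
#'   statistic, the p value, and `significant = p < alpha`.
#' @export
compare_strategies <- function(curve, a, b, alpha = 0.05,
                               var_equal = FALSE) {
  if (!inherits(curve, "hazard_curve"))
    stop("`curve` must be a hazard_curve", call. = FALSE)
  for (s in c(a, b))
    if (!s %in% curve$strategies)
      stop("unknown strategy: ", s, call. = FALSE)
  if (curve$n_runs < 2)
    stop("need at least 2 runs per cell for a t-test", call. = FALSE)
  out <- lapply(seq_along(curve$d_f_grid), function(j) {
    xa <- curve$fractions[, j, a]
    xb <- curve$fractions[, j, b]
    tt <- tryCatch(stats::t.test(xa, xb, var.equal = var_equal),
                   error = function(e) NULL)   # both samples constant
    if (is.null(tt)) {
      t_stat <- if (mean(xa) == mean(xb)) 0 else Inf * sign(mean(xa) -
                                                              mean(xb))
      p <- if (mean(xa) == mean(xb)) 1 else 0
    } else {
      t_stat <- unname(tt$statistic)
      p <- tt$p.value
    }
    data.frame(d_f = curve$d_f_grid[j], mean_a = mean(xa),
               mean_b = mean(xb), t = t_stat, p_value = p,
               significant = p < alpha)
  })
  do.call(rbind, out)
}

#' Locate the hazard phase transition
#'
#' The hazard curve of an effective strategy drops from a high to a low
#' plateau as the break density crosses a critical value.  The detector
#' takes the high plateau as the mean of the first two grid points and
#' the low plateau as the mean of the last two, and returns the break
#' density at which the curve first crosses the midpoint of the two,
#' linearly interpolated between the bracketing grid points.
#'
#' @param curve A [hazard_campaign()] result, or a numeric vector of
#'   mean hazards (then `d_f` must be given).
#' @param strategy Which strategy's curve to analyse (required when
#'   `curve` is a `hazard_curve` with several).
#' @param d_f Break-density grid matching a numeric `curve`.
#' @return The interpolated transition density `d_f*`.  Signals an
#'   error of class `no_transition` when the curve never crosses the
#'   midpoint.
#' @examples
#' detect_transition(c(1, 1, 0.9, 0.1, 0, 0), d_f = seq(0, 0.5, 0.1))
#' @export
detect_transition <- function(curve, strategy = NULL, d_f = NULL) {
  if (inherits(curve, "hazard_curve")) {
    if (is.null(strategy)) {
      if (length(curve$strategies) > 1)
        stop("specify `strategy` for a multi-strategy curve",
             call. = FALSE)
      strategy <- curve$strategies[1]
    }
    R <- curve$mean_R[, strategy]
    d_f <- curve$d_f_grid
  } else {
    R <- as.numeric(curve)
    if (is.null(d_f) || length(d_f) != length(R))
      stop("`d_f` must accompany a numeric curve", call. = FALSE)
  }
  if (length(R) < 4)
    stop("need at least 4 grid points to estimate both plateaus",
         call. = FALSE)
  r_high <- mean(R[1:2])
  r_low <- mean(R[c(length(R) - 1, length(R))])
  thr <- (r_high + r_low) / 2
  below <- which(R < thr)
  if (!length(below))
    stop(structure(
      list(message = "curve never crosses the plateau midpoint",
           call = sys.call()),
      class = c("no_transition", "error", "condition")))
  i <- below[1]
  if (i == 1) return(d_f[1])
  # linear interpolation on the bracketing segment
  d_f[i - 1] + (R[i - 1] - thr) / (R[i - 1] - R[i]) * (d_f[i] - d_f[i - 1])
}

#' Burning-frequency map
#'
#' Repeats a fire `n_runs` times from the same ignition cell and maps
#' how often each cell burned.  The nonzero relative frequencies are
#' histogrammed into 16 equal-width bins spanning `(0, max]`, and the
#' bins are assigned -- in descending order -- the 16 gray levels 256,
#' 240, ..., 16, so the most frequently burned cells are darkest.
#' Cells that never burned stay outside the bins (gray `NA`,
#' rendered as white 255 on export).  The nominal top level 256 is
#' clamped to 255 on 8-bit image export; the numeric map keeps the
#' exact levels.
#'
#' @param grid A [landscape_grid].
#' @param plan Optional `firebreak_plan` applied before the runs.
#' @param ignition Ignition cell (see [run_fire()]).
#' @param n_runs Number of repeated fires.
#' @param base_seed Seed; run `i` uses `base_seed + i`.
#' @param params [ca_params()] for full-model grids.
#' @return A `frequency_map`: `counts`, `freq` (counts / n_runs),
#'   `gray` (quantized levels, `NA` where never burned), `n_runs`.
#' @export
burning_frequency_map <- function(grid, plan = NULL, ignition = "center",
                                  n_runs = 100, base_seed = 1,
                                  params = NULL) {
  if (n_runs < 1) stop("`n_runs` must be at least 1", call. = FALSE)
  if (!is.null(plan)) grid <- apply_breaks(grid, plan)
  counts <- matrix(0L, grid$n_rows, grid$n_cols)
  dir_probs <- direction_probs(grid, params)
  for (i in seq_len(n_runs)) {
    sim <- run_fire_cached(grid, ignition, seed = base_seed + i, params,
                           dir_probs)
    counts <- counts + sim$burned_mask
  }
  freq <- counts / n_runs
  gray <- matrix(NA_real_, grid$n_rows, grid$n_cols)
  if (any(freq > 0)) {
    fmax <- max(freq)
    nz <- freq > 0
    bin <- pmin(pmax(ceiling(freq[nz] / fmax * 16), 1), 16)
    gray[nz] <- 256 - (bin - 1) * 16
  }
  structure(list(counts = counts, freq = freq, gray = gray,
                 n_runs = n_runs, ignition = resolve_ignition(grid,
                                                              ignition)),
            class = "frequency_map")
}

#' @export
print.frequency_map <- function(x, ...) {
  cat(sprintf(
    "frequency_map: %d x %d cells over %d runs; %d cells ever burned\n",
    nrow(x$counts), ncol(x$counts), x$n_runs, sum(x$counts > 0)))
  if (any(x$counts > 0))
    cat(sprintf("  burn frequency range (burned cells): [%.3g, %.3g]\n",
                min(x$freq[x$freq > 0]), max(x$freq)))
  invisible(x)
}

#' @rdname burning_frequency_map
#' @param map A `frequency_map`.
#' @param path Output path (plain PGM).
#' @export
write_frequency_map <- function(map, path) {
  g <- map$gray
  g[is.na(g)] <- 255
  write_pgm(g, path)
}

#' Export a hazard curve as CSV
#'
#' One row per (strategy, d_f): achieved break density, mean hazard,
#' 90th percentile, run count, and -- when `reference` names one of the
#' strategies -- the Welch p value against it.
#'
#' @param curve A [hazard_campaign()] result.
#' @param path Output path.
#' @param reference Optional reference strategy for p values.
#' @export
write_curve_csv <- function(curve, path, reference = NULL) {
  df <- as.data.frame(curve)
  if (!is.null(reference)) {
    df$p_value <- NA_real_
    for (s in setdiff(curve$strategies, reference)) {
      cmp <- compare_strategies(curve, s, reference)
      df$p_value[df$strategy == s] <- cmp$p_value
    }
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
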