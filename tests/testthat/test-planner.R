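test_that("centrality placement sweeps the ranking under the constraint", {
  g <- artificial_forest(3, seed = 1)
  scores <- rep(0, 9)
  scores[node_index(2, 2, g)] <- 1    # centre ranked first

  expect_length(place_by_centrality(g, scores, 0)$removed, 0)

  # with the Moore constraint all 8 neighbours become ineligible, so on
  # a 3x3 torus only the centre can ever be selected
  plan <- place_by_centrality(g, scores, 1, exclusion = "moore")
  expect_identical(plan$removed, node_index(2, 2, g))
  expect_equal(plan$d_f_achieved, 1 / 9)
  expect_lt(plan$d_f_achieved, plan$d_f_target)

  # rook constraint keeps the diagonal neighbours available
  plan_r <- place_by_centrality(g, scores, 1, exclusion = "rook")
  expect_true(node_index(2, 2, g) %in% plan_r$removed)
  expect_false(rook_adjacent_pair(plan_r$removed, g))

  expect_error(place_by_centrality(g, scores, 1.2), "\\[0, 1\\]")
  expect_error(place_by_centrality(g, scores[1:4], 0.1), "cover all")
})

test_that("uniform scores give a maximal non-adjacent set in index order", {
  g <- artificial_forest(4, seed = 1)
  plan <- place_by_centrality(g, rep(1, 16), 1, exclusion = "moore")
  # greedy on ties walks ascending node index; on a 4x4 torus the
  # index-order maximal Moore-independent set is {1, 3, 9, 11}, one
  # break per 2x2 block (the packing limit of 1/4)
  expect_identical(plan$removed, c(1L, 3L, 9L, 11L))
  expect_false(moore_adjacent_pair(plan$removed, g))
  # verify maximality: every unselected flammable node is adjacent to
  # a selected one
  rest <- setdiff(seq_len(16), plan$removed)
  nb_all <- unique(unlist(lapply(plan$removed, function(k)
    firebreaks:::neighbor_indices(k, g, "moore"))))
  expect_true(all(rest %in% nb_all))
})

test_that("selected scores dominate skipped-but-eligible nodes", {
  for (seed in 1:4) {
    g <- artificial_forest(7, seed = seed)
    set.seed(seed + 100)
    scores <- runif(49)
    plan <- place_by_centrality(g, scores, 0.15, exclusion = "rook")
    # replay the sweep: at each pick, no eligible node scores higher
    eligible <- as.vector(t(flammable_cells(g)))
    for (k in plan$removed) {
      better <- which(eligible & scores > scores[k])
      expect_length(better, 0)
      eligible[k] <- FALSE
      eligible[firebreaks:::neighbor_indices(k, g, "rook")] <- FALSE
    }
  }
})

test_that("random placement is seeded, uniform and constraint-capable", {
  g <- artificial_forest(6, seed = 9)
  expect_length(place_random(g, 0, seed = 1)$removed, 0)
  p1 <- place_random(g, 0.2, seed = 7)
  p2 <- place_random(g, 0.2, seed = 7)
  expect_identical(p1$removed, p2$removed)
  expect_false(identical(p1$removed, place_random(g, 0.2, seed = 8)$removed))

  # one-break draws hit each node with frequency 1/n_v
  n_v <- sum(flammable_cells(g))
  picks <- vapply(seq_len(1e4), function(i)
    place_random(g, 1 / n_v, seed = 20000 + i)$removed[1], integer(1))
  freq <- tabulate(picks, nbins = 36) / 1e4
  se <- sqrt((1 / n_v) * (1 - 1 / n_v) / 1e4)
  expect_true(all(abs(freq - 1 / n_v) < 3.5 * se))

  # constrained variants respect their exclusion rule
  pr <- place_random(g, 0.5, seed = 3, exclusion = "rook")
  expect_false(rook_adjacent_pair(pr$removed, g))
  pm <- place_random(g, 0.5, seed = 3, exclusion = "moore")
  expect_false(moore_adjacent_pair(pm$removed, g))
})

test_that("plans never contain adjacent breaks under their constraint", {
  for (seed in 1:6) {
    g <- artificial_forest(9, seed = seed)
    set.seed(seed)
    scores <- runif(81)
    d_f <- runif(1, 0.05, 0.5)
    pr <- place_by_centrality(g, scores, d_f, exclusion = "rook")
    expect_false(rook_adjacent_pair(pr$removed, g))
    pm <- place_by_centrality(g, scores, d_f, exclusion = "moore")
    expect_false(moore_adjacent_pair(pm$removed, g))
    # absorbing boundaries too (no wrap-around adjacency)
    land <- synthetic_landscape(9, seed = seed)
    pc <- place_breaks(land, conventional_ranking(land), d_f,
                       exclusion = "moore")
    expect_false(moore_adjacent_pair(pc$removed, land))
  }
})

test_that("forbidden nodes (ignition cells) are never removed", {
  g <- artificial_forest(8, seed = 2)
  centre <- node_index(4, 4, g)
  plan <- place_by_centrality(g, rep(1, 64), 1, forbidden = centre)
  expect_false(centre %in% plan$removed)
  pr <- place_random(g, 1, seed = 5, forbidden = centre)
  expect_false(centre %in% pr$removed)
})

test_that("the conventional ranking orders vegetation classes correctly", {
  land <- synthetic_landscape(4, seed = 1, p_bare = 0)
  # overwrite categories with a hand-built mixed fixture (row-major)
  types <- c("pine", "other", "pine", "other",
             "pine", "other", "pine", "other",
             "agricultural", "agricultural", "pine", "other",
             "pine", "other", "agricultural", "pine")
  dens <- c("dense", "dense", "moderate", "moderate",
            "sparse", "sparse", "dense", "dense",
            "dense", "sparse", "moderate", "moderate",
            "sparse", "sparse", "moderate", "dense")
  land$type_cat <- matrix(types, 4, 4, byrow = TRUE)
  land$density_cat <- matrix(dens, 4, 4, byrow = TRUE)
  land$type_effect <- matrix(ca_params()$type_effects[types], 4, 4,
                             byrow = TRUE)
  land$density_effect <- matrix(ca_params()$density_effects[dens], 4, 4,
                                byrow = TRUE)
  r <- conventional_ranking(land)
  # hand-computed classes: dense pine {1,7,16}, dense other {2,8},
  # moderate pine {3,11}, moderate other {4,12}, sparse pine {5,13},
  # sparse other {6,14}, agricultural {9,10,15}; index order within
  expect_identical(r, as.integer(c(1, 7, 16, 2, 8, 3, 11, 4, 12,
                                   5, 13, 6, 14, 9, 10, 15)))

  # all cells in one class: ranking reduces to index order
  land$type_cat[] <- "pine"; land$density_cat[] <- "dense"
  expect_identical(conventional_ranking(land), seq_len(16L))
  expect_error(conventional_ranking(artificial_forest(4)), "full-model")
})

test_that("applying breaks clears fuel without touching burn states", {
  g <- artificial_forest(5, seed = 3)
  empty_plan <- place_random(g, 0, seed = 1)
  expect_identical(apply_breaks(g, empty_plan), g)

  scores <- rep(0, 25); scores[13] <- 1
  plan <- place_by_centrality(g, scores, 1 / 25)
  g2 <- apply_breaks(g, plan)
  expect_equal(g2$emptiness[3, 3], 1)
  g2$emptiness[3, 3] <- g$emptiness[3, 3]
  expect_identical(g2, g)

  # the treated network has no edges touching the removed node
  net <- build_network(apply_breaks(g, plan))
  expect_equal(Matrix::colSums(net$adjacency)[13], 0)
  expect_equal(Matrix::rowSums(net$adjacency)[13], 0)

  # full model: flammability flag drops instead
  land <- synthetic_landscape(5, seed = 4, p_bare = 0)
  lplan <- place_breaks(land, conventional_ranking(land), 1 / 25)
  l2 <- apply_breaks(land, lplan)
  expect_false(all(l2$flammable))
  expect_identical(l2$burn_state, land$burn_state)
})

test_that("plans serialise to JSON and masks round-trip", {
  g <- artificial_forest(6, seed = 5)
  plan <- place_random(g, 0.2, seed = 11, exclusion = "rook")
  path <- tempfile(fileext = ".json")
  write_plan(plan, path)
  back <- read_plan(path)
  expect_identical(back$removed, plan$removed)
  expect_equal(back$d_f_achieved, plan$d_f_achieved)
  expect_identical(back$strategy, plan$strategy)
  expect_identical(back$exclusion, plan$exclusion)

  mask <- plan_mask(plan, g)
  expect_equal(sum(mask), length(plan$removed))
  expect_setequal(which(as.vector(t(mask)) == 1L), plan$removed)
})
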