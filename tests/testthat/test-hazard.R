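test_that("hazard intensity is the mean burned fraction", {
  expect_equal(hazard_intensity(rep(100, 5), 100), 1)
  expect_equal(hazard_intensity(c(0, 100), 100), 0.5)
  expect_equal(hazard_intensity(c(10, 20, 30), 100), 0.2)
  expect_error(hazard_intensity(numeric(0), 10), "non-empty")
  expect_error(hazard_intensity(c(-1, 3), 10), "non-negative")
})

test_that("degenerate campaigns reduce to single simulations", {
  # all-dense forest, no breaks: deterministic total spread, R = 1
  dense_gen <- function(seed) {
    g <- artificial_forest(7, seed = seed)
    g$emptiness[] <- 0
    g
  }
  hc <- hazard_campaign(dense_gen, list(rand = strategy_random()),
                        d_f_grid = 0, n_runs = 3, base_seed = 1)
  expect_equal(as.vector(hc$fractions), rep(1, 3))
  expect_equal(unname(hc$mean_R[1, 1]), 1)

  # one run, d_f = 0: exactly run_fire on the generated forest
  gen <- function(seed) artificial_forest(15, seed = seed)
  hc1 <- hazard_campaign(gen, list(rand = strategy_random()),
                         d_f_grid = 0, n_runs = 1, base_seed = 3)
  direct <- run_fire(gen(3 + 1), "center", seed = 3 + 500000 + 1)
  expect_equal(unname(hc1$fractions[1, 1, 1]), direct$n_burned / 225)
})

test_that("campaigns are bit-reproducible and record achieved densities", {
  gen <- function(seed) artificial_forest(12, seed = seed)
  sts <- list(bona = strategy_centrality("bonacich", 0.5),
              rand = strategy_random())
  h1 <- hazard_campaign(gen, sts, d_f_grid = c(0, 0.1, 0.3),
                        n_runs = 5, base_seed = 17)
  h2 <- hazard_campaign(gen, sts, d_f_grid = c(0, 0.1, 0.3),
                        n_runs = 5, base_seed = 17)
  expect_identical(h1$fractions, h2$fractions)
  expect_true(all(h1$fractions >= 0 & h1$fractions <= 1))
  expect_equal(h1$d_f_achieved[1, ], c(bona = 0, rand = 0))
  expect_lt(abs(h1$d_f_achieved[2, "rand"] - 0.1), 0.01)
  # percentiles bracket the mean
  expect_true(all(h1$p90 >= h1$mean_R - 1e-12))
  for (s in 1:2) for (j in 1:3) {
    expect_gte(h1$mean_R[j, s], min(h1$fractions[, j, s]))
    expect_lte(h1$mean_R[j, s], max(h1$fractions[, j, s]))
  }
})

test_that("mean hazard responds monotonically to nested break plans", {
  gen <- function(seed) artificial_forest(20, seed = seed)
  hc <- hazard_campaign(gen, list(bona = strategy_centrality("bonacich",
                                                             0.5)),
                        d_f_grid = seq(0, 0.4, 0.1), n_runs = 25,
                        base_seed = 23)
  # common random numbers: means may wobble within Monte-Carlo noise
  # but never increase materially with more breaks
  expect_true(all(diff(hc$mean_R[, 1]) < 0.05))
})

test_that("strategy comparison implements the Welch test", {
  gen <- function(seed) artificial_forest(15, seed = seed)
  sts <- list(a = strategy_random(), b = strategy_random())
  hc <- hazard_campaign(gen, sts, d_f_grid = c(0, 0.2), n_runs = 10,
                        base_seed = 5)
  cmp <- compare_strategies(hc, "a", "b")
  # identical samples (same seeds, same strategy): t = 0, never flagged
  expect_equal(cmp$t, c(0, 0))
  expect_equal(cmp$p_value, c(1, 1))
  expect_false(any(cmp$significant))

  # separated samples: reproduce the textbook Welch formulas exactly
  hc$fractions[, 2, "a"] <- seq(0.85, 0.95, length.out = 10)
  hc$fractions[, 2, "b"] <- seq(0.05, 0.18, length.out = 10)
  cmp2 <- compare_strategies(hc, "a", "b")
  ora <- oracle_welch(hc$fractions[, 2, "a"], hc$fractions[, 2, "b"])
  expect_equal(cmp2$t[2], ora$t, tolerance = 1e-10)
  expect_equal(cmp2$p_value[2], ora$p, tolerance = 1e-10)
  expect_true(cmp2$significant[2])
  expect_error(compare_strategies(hc, "a", "zzz"), "unknown strategy")
})

test_that("the transition detector interpolates the midpoint crossing", {
  # step curve dropping between grid points brackets the crossing
  d <- seq(0, 0.5, 0.1)
  step <- c(1, 1, 1, 0, 0, 0)
  expect_equal(detect_transition(step, d_f = d), 0.25)
  # linear descent crosses the midpoint halfway
  lin <- seq(1, 0, length.out = 11)
  expect_equal(detect_transition(lin, d_f = seq(0, 1, 0.1)), 0.5)
  # analytic logistic with midpoint 0.22 sampled at 0.02 resolution
  dd <- seq(0, 0.5, 0.02)
  logi <- plogis(-(dd - 0.22) / 0.03)
  expect_lt(abs(detect_transition(logi, d_f = dd) - 0.22), 0.01)
  # flat curve: dedicated condition class
  expect_error(detect_transition(rep(1, 6), d_f = seq(0, 1, 0.2)),
               class = "no_transition")
})

test_that("burning-frequency maps quantize to 16 descending gray levels", {
  # deterministic full burn: single bin at the darkest level
  g <- artificial_forest(7, seed = 1)
  g$emptiness[] <- 0
  fm <- burning_frequency_map(g, n_runs = 5, base_seed = 1)
  expect_true(all(fm$counts == 5))
  expect_equal(unique(as.vector(fm$gray)), 16)

  # isolated ignition: everything else never burns, background NA
  g$emptiness[] <- 1
  g$emptiness[4, 4] <- 0.5
  fm2 <- burning_frequency_map(g, n_runs = 8, base_seed = 2)
  expect_equal(fm2$counts[4, 4], 8)
  expect_true(all(fm2$counts[-(node_index(4, 4, g))] == 0))
  expect_true(all(is.na(fm2$gray[-(node_index(4, 4, g))])))

  # hand-built frequencies 1.0 and 0.5: two gray levels, higher
  # frequency darker (16 vs 144)
  g3 <- artificial_forest(5, seed = 3)
  g3$emptiness[] <- 1
  g3$emptiness[3, 3] <- 0      # always burns (ignition)
  g3$emptiness[3, 4] <- 0.5    # burns about half the runs
  fm3 <- burning_frequency_map(g3, n_runs = 200, base_seed = 4)
  expect_equal(fm3$freq[3, 3], 1)
  expect_lt(abs(fm3$freq[3, 4] - 0.5), 0.12)
  expect_equal(fm3$gray[3, 3], 16)
  # about half the top frequency: a clearly lighter mid-scale level
  expect_gt(fm3$gray[3, 4], fm3$gray[3, 3])
  expect_true(fm3$gray[3, 4] %in% seq(96, 160, by = 16))

  # export renders background white and clamps to 8 bits
  path <- tempfile(fileext = ".pgm")
  write_frequency_map(fm3, path)
  img <- read_pgm(path)
  expect_equal(img[1, 1], 255)
  expect_equal(img[3, 3], 16)
  expect_true(all(img >= 0 & img <= 255))
})

test_that("multi-ignition campaigns draw flammable ignitions uniformly", {
  land <- synthetic_landscape(15, seed = 6)
  hc <- hazard_campaign(land,
                        list(conv = strategy_conventional()),
                        d_f_grid = c(0, 0.1), n_runs = 12,
                        mode = "multi_ignition", base_seed = 9)
  expect_equal(dim(hc$fractions), c(12, 2, 1))
  expect_true(all(hc$fractions >= 0 & hc$fractions <= 1))
  # no-break column must burn at least the ignition cell
  expect_true(all(hc$fractions[, 1, 1] > 0))
  expect_error(
    hazard_campaign(artificial_forest(5),
                    list(r = strategy_random()), d_f_grid = 0,
                    n_runs = 2, mode = "ensemble"),
    "generator")
})

test_that("hazard curves export to CSV with optional p values", {
  gen <- function(seed) artificial_forest(10, seed = seed)
  hc <- hazard_campaign(gen, list(bona = strategy_centrality(),
                                  rand = strategy_random()),
                        d_f_grid = c(0, 0.2), n_runs = 4, base_seed = 2)
  path <- tempfile(fileext = ".csv")
  write_curve_csv(hc, path, reference = "rand")
  df <- utils::read.csv(path)
  expect_named(df, c("strategy", "d_f", "d_f_achieved", "mean_R", "p90",
                     "n_runs", "p_value"))
  expect_equal(nrow(df), 4)
  expect_true(all(is.na(df$p_value[df$strategy == "rand"])))
  expect_true(all(!is.na(df$p_value[df$strategy == "bona"])))
})
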