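test_that("knockout zeroes exactly one beta row and copies the rest", {
  sys <- random_fixture_system(n = 12, m = 20, seed = 7)
  ep <- sys$params
  j <- which(Matrix::rowSums(ep$beta != 0) > 0)[1]
  ko <- knockout(ep, j)
  expect_true(all(ko$beta[j, ] == 0))
  expect_equal(as.matrix(ko$beta)[-j, ], as.matrix(ep$beta)[-j, ])
  # original untouched
  expect_gt(sum(ep$beta[j, ] != 0), 0)
  # knocking out a gene with no outgoing edges changes nothing
  leaf <- which(Matrix::rowSums(ep$beta != 0) == 0)[1]
  expect_identical(as.matrix(knockout(ep, leaf)$beta), as.matrix(ep$beta))
})

test_that("chain knockout reproduces the scalar fixed-point oracle", {
  ep <- two_gene_chain(s = 0)
  base <- simulate_to_steady_state(ep, seed = 1)
  screen <- knockout_screen(ep, base, seed = 2)
  # oracle: both conditions via independent fixed-point iteration
  x_base <- fixed_point_oracle(ep)
  x_ko <- fixed_point_oracle(knockout(ep, 1))
  expect_equal(screen$log2fc[1, 2], log2(x_ko[2] / x_base[2]),
               tolerance = 1e-3)
  # gene 2 reverts to its regulator-free fixed point sigmoid(alpha)/ell
  expect_equal(x_ko[2], 0.25, tolerance = 1e-9)
  expect_true(is.na(screen$log2fc[1, 1]))
})

test_that("screen equals gene-by-gene runs on matching streams", {
  sys <- random_fixture_system(n = 15, m = 25, seed = 31)
  ep <- sys$params
  cfg <- fast_config()
  base <- simulate_to_steady_state(ep, cfg, seed = 40)
  screen <- knockout_screen(ep, base, cfg, seed = 41)
  for (j in c(1, 7, 15)) {
    one <- simulate_to_steady_state(knockout(ep, j), cfg, seed = 41,
                                    init = base$xbar, stream = j - 1)
    lf <- log2(pmax(one$xbar, .Machine$double.eps)) -
      log2(pmax(base$xbar, .Machine$double.eps))
    expect_equal(unname(screen$log2fc[j, -j]), lf[-j], tolerance = 1e-12)
  }
})

test_that("knocking out an isolated gene has no measurable effect", {
  b <- matrix(0, 3, 3)
  b[1, 2] <- 2
  ep <- expression_params(alpha = rep(qlogis(0.2), 3), ell = rep(0.8, 3),
                          beta = b, s = 1e-4)
  base <- simulate_to_steady_state(ep, fast_config(), seed = 3)
  screen <- knockout_screen(ep, base, fast_config(), seed = 4)
  expect_lt(max(abs(screen$log2fc[3, -3])), 1e-3)
})

test_that("hub counts match constructed cases and a brute-force oracle", {
  lf <- matrix(0, 200, 200)
  diag(lf) <- NA
  expect_equal(hub_counts(lf, 0.1, 100)$n_hub_ko, 0)
  expect_equal(hub_counts(lf, 0.1, 100)$n_hub_target, 0)

  lf[1, 2:151] <- 0.2  # gene 1 affects 150 genes
  h <- hub_counts(lf, 0.1, 100)
  expect_equal(h$n_hub_ko, 1)
  expect_equal(h$n_hub_target, 0)

  set.seed(9)
  lf <- matrix(rnorm(50 * 50, sd = 0.2), 50, 50)
  diag(lf) <- NA
  expressed <- runif(50) > 0.2
  h <- hub_counts(lf, 0.15, 5, expressed = expressed)
  # nested-loop oracle
  idx <- which(expressed)
  ko <- tgt <- 0
  for (j in idx) {
    cnt <- sum(abs(lf[j, setdiff(idx, j)]) > 0.15)
    if (cnt >= 5) ko <- ko + 1
  }
  for (i in idx) {
    cnt <- sum(abs(lf[setdiff(idx, i), i]) > 0.15)
    if (cnt >= 5) tgt <- tgt + 1
  }
  expect_equal(h$n_hub_ko, ko)
  expect_equal(h$n_hub_target, tgt)
})

test_that("effect stratification partitions pairs and matches a loop oracle", {
  sys <- random_fixture_system(n = 30, m = 60, k = 3, seed = 13)
  ep <- sys$params
  cfg <- fast_config()
  base <- simulate_to_steady_state(ep, cfg, seed = 14)
  screen <- knockout_screen(ep, base, cfg, seed = 15)
  d <- shortest_path_distances(sys$graph)
  strat <- stratify_effects(screen, d, sys$graph$group, effect_thresh = 0.01)

  idx <- which(screen$expressed)
  n_exp <- length(idx)
  expect_equal(strat$n_pairs, n_exp * (n_exp - 1))
  expect_equal(sum(lengths(strat$effects_by_distance)), strat$n_pairs)
  expect_equal(length(strat$within) + length(strat$across), strat$n_pairs)
  expect_equal(length(strat$direct) + length(strat$mediated), strat$n_pairs)

  # loop oracle for the direct-pair exceedance fraction
  hits <- tot <- 0
  for (j in idx) for (i in idx) {
    if (i == j || d[j, i] != 1) next
    tot <- tot + 1
    hits <- hits + (abs(screen$log2fc[j, i]) > 0.01)
  }
  expect_equal(strat$direct_exceed, hits / tot)

  # direct effects dominate mediated ones
  expect_gt(median(strat$direct), median(strat$mediated))
})

test_that("chain effects are classified as mediated beyond distance 1", {
  b <- matrix(0, 3, 3)
  b[1, 2] <- 2
  b[2, 3] <- 2
  ep <- expression_params(alpha = rep(qlogis(0.2), 3), ell = rep(0.8, 3),
                          beta = b, s = 0)
  base <- simulate_to_steady_state(ep, fast_config(), seed = 1)
  screen <- knockout_screen(ep, base, fast_config(), seed = 2)
  g <- as_grn_graph(3, rbind(c(1, 2), c(2, 3)))
  strat <- stratify_effects(screen, shortest_path_distances(g), g$group,
                            effect_thresh = 0.01)
  # the 1 -> 3 effect exists and lives in the distance-2 stratum
  expect_gt(abs(screen$log2fc[1, 3]), 0.01)
  expect_true(2 %in% strat$distance_levels)
  expect_gt(strat$exceed_by_distance[["2"]], 0)
})

test_that("cell sampling is noise-driven and mean-centred on the baseline", {
  sys <- random_fixture_system(n = 10, m = 15, seed = 17, s = 0)
  base <- simulate_to_steady_state(sys$params, fast_config(), seed = 18)
  cells0 <- sample_cells(sys$params, base, n_steps = 50, seed = 19)
  expect_identical(nrow(cells0$cells), 50L)
  # s = 0: every cell equals the deterministic trajectory limit
  expect_lt(max(abs(sweep(cells0$cells, 2, base$xbar))), 1e-5)

  noisy <- sys$params
  noisy$s <- 1e-2
  basen <- simulate_to_steady_state(noisy, fast_config(), seed = 18)
  cells <- sample_cells(noisy, basen, n_steps = 4000, seed = 20)
  expect_gt(max(apply(cells$cells, 2, sd)), 0)
  expect_lt(max(abs(colMeans(cells$cells) - basen$xbar) /
                  pmax(basen$xbar, 1e-6)), 0.05)
})

test_that("coexpression matches a two-pass Pearson oracle", {
  set.seed(8)
  m <- matrix(rnorm(50), 10, 5)
  m <- cbind(m, m[, 2])  # duplicated column pair
  cc <- coexpression(m)
  expect_equal(cc[2, 6], 1)
  expect_true(all(diag(cc) == 1))
  # textbook two-pass oracle
  oracle <- matrix(NA_real_, 6, 6)
  for (i in 1:6) for (j in 1:6) {
    xi <- m[, i] - mean(m[, i]); xj <- m[, j] - mean(m[, j])
    oracle[i, j] <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
  }
  expect_equal(unname(cc), oracle, tolerance = 1e-12)
  expect_error(coexpression(m[1, , drop = FALSE]), "2 cells")
  # zero-variance gene flagged undefined
  m2 <- cbind(m, 1)
  expect_true(all(is.na(coexpression(m2)[7, -7])))
})
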