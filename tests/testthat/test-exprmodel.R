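test_that("sampled parameters satisfy the model's constraints", {
  g <- generate_network(graph_params(n = 400, k = 5, w = 9, p = 0.25,
                                     delta_in = 10, delta_out = 3, seed = 10))
  ep <- sample_expression_params(g, seed = 11)
  # sparsity pattern matches the edge set exactly
  tr <- Matrix::summary(ep$beta)
  expect_setequal(paste(tr$i, tr$j), paste(g$edges[, 1], g$edges[, 2]))
  expect_true(all(abs(tr$x) >= 1))
  expect_true(all(ep$ell > 0))
  # the decay floor binds whenever the Beta draw falls below exp(-alpha)
  expect_true(all(ep$ell >= exp(-ep$alpha) - 1e-12))
  # one sign per regulator: outgoing edges of a gene agree in sign
  sgn <- tapply(sign(tr$x), tr$i, function(v) length(unique(v)))
  expect_true(all(sgn == 1))
  # determinism
  ep2 <- sample_expression_params(g, seed = 11)
  expect_identical(ep$beta, ep2$beta)
})

test_that("about 80% of regulators are activators", {
  g <- random_fixture_graph(500, 2000, k = 1, seed = 2)
  ep <- sample_expression_params(g, seed = 3)
  tr <- Matrix::summary(ep$beta)
  reg_sign <- tapply(sign(tr$x), tr$i, unique)
  expect_lt(abs(mean(reg_sign > 0) - 0.8), 0.06)
})

test_that("an edgeless graph still gets alpha and ell but a zero beta", {
  g <- as_grn_graph(5, matrix(integer(0), 0, 2))
  ep <- sample_expression_params(g, seed = 1)
  expect_identical(length(ep$beta@x), 0L)
  expect_length(ep$alpha, 5)
  expect_true(all(ep$ell > 0))
})

test_that("step reproduces hand-computed updates", {
  # isolated gene, sigmoid(alpha) = 0.2, ell = 0.8, from x = 0:
  # x' = 0 + 0.01 * (0.2 - 0) = 0.002
  ep <- expression_params(alpha = qlogis(0.2), ell = 0.8,
                          beta = matrix(0, 1, 1), s = 0)
  expect_equal(step(0, ep), 0.002)
  # zero drift at the fixed point
  expect_equal(step(0.25, ep), 0.25)
  expect_error(step(NaN, ep), "non-finite")
})

test_that("step matches a scalar loop-free oracle on a two-gene system", {
  ep <- two_gene_chain(s = 0)
  x <- c(0.3, 0.7)
  # per-gene scalar recomputation
  u1 <- qlogis(0.2)                 # gene 1 has no regulators
  u2 <- qlogis(0.2) + 2 * x[1]      # gene 2 regulated by gene 1
  expected <- c(x[1] + 0.01 * (plogis(u1) - 0.8 * x[1]),
                x[2] + 0.01 * (plogis(u2) - 0.8 * x[2]))
  expect_equal(step(x, ep), expected)
})

test_that("compiled simulator agrees with the R kernel in the deterministic limit", {
  sys <- random_fixture_system(n = 15, m = 25, seed = 8, s = 0)
  ep <- sys$params
  traj <- grnforge:::cpp_record_steps(grnforge:::beta_transpose(ep),
                                      ep$alpha, ep$ell, 0, ep$dt,
                                      numeric(ep$n), 50L, 1, 0, -1L)
  x <- numeric(ep$n)
  for (i in 1:50) x <- step(x, ep)
  expect_equal(as.numeric(traj[, 50]), x, tolerance = 1e-12)
})

test_that("isolated gene converges to sigmoid(alpha)/ell", {
  ep <- expression_params(alpha = qlogis(0.2), ell = 0.8,
                          beta = matrix(0, 1, 1), s = 0)
  ss <- simulate_to_steady_state(ep, seed = 1)
  expect_true(ss$converged)
  expect_equal(ss$xbar, 0.25, tolerance = 1e-4)
})

test_that("two-gene chain converges to the fixed-point oracle", {
  ep <- two_gene_chain(s = 0)
  ss <- simulate_to_steady_state(ep, seed = 1)
  oracle <- fixed_point_oracle(ep)
  expect_equal(ss$xbar, oracle, tolerance = 1e-3)
  # downstream gene sits near sigmoid(logit(0.2) + 2 * 0.25) / 0.8
  expect_equal(ss$xbar[2], plogis(qlogis(0.2) + 2 * 0.25) / 0.8,
               tolerance = 1e-3)
})

test_that("simulation is bit-reproducible and seed-sensitive", {
  sys <- random_fixture_system(n = 20, m = 30, seed = 4)
  a <- simulate_to_steady_state(sys$params, fast_config(), seed = 5)
  b <- simulate_to_steady_state(sys$params, fast_config(), seed = 5)
  c <- simulate_to_steady_state(sys$params, fast_config(), seed = 6)
  expect_identical(a$xbar, b$xbar)
  expect_false(identical(a$xbar, c$xbar))
})

test_that("low noise steady state tracks the deterministic fixed point", {
  sys <- random_fixture_system(n = 25, m = 40, seed = 12, s = 1e-4)
  ss <- simulate_to_steady_state(sys$params, seed = 2)
  det <- sys$params
  det$s <- 0
  ss0 <- simulate_to_steady_state(det, seed = 2)
  expect_true(ss$converged)
  expect_lt(max(abs(ss$xbar - ss0$xbar)), 1e-2)
  # fixed-point residual is small after convergence
  expect_lt(max(abs(fixed_point_residual(sys$params, ss0$xbar))), 1e-2)
})

test_that("states remain non-negative under noise", {
  sys <- random_fixture_system(n = 10, m = 15, seed = 3, s = 0.5)
  traj <- grnforge:::cpp_record_steps(grnforge:::beta_transpose(sys$params),
                                      sys$params$alpha, sys$params$ell,
                                      0.5, 0.01, numeric(10), 2000L, 9, 0, -1L)
  expect_true(all(traj >= 0))
})

test_that("fixed_point_residual reproduces hand values", {
  ep <- expression_params(alpha = qlogis(0.2), ell = 0.8,
                          beta = matrix(0, 1, 1), s = 0)
  expect_equal(fixed_point_residual(ep, 0.25), 0)
  expect_equal(fixed_point_residual(ep, 0), -0.25)
})

test_that("Jacobian spectrum is correct for analytic cases", {
  ep1 <- expression_params(alpha = qlogis(0.2), ell = 0.8,
                           beta = matrix(0, 1, 1), s = 0)
  st <- stability_analysis(ep1, 0.25)
  expect_equal(Re(st$values), -0.8)
  expect_true(st$stable)

  ep2 <- two_gene_chain(s = 0)
  xbar <- fixed_point_oracle(ep2)
  st2 <- stability_analysis(ep2, xbar)
  expect_equal(sort(Re(st2$values)), c(-0.8, -0.8))
  expect_true(st2$stable)
})

test_that("Jacobian matches naive entry-by-entry assembly on a random system", {
  sys <- random_fixture_system(n = 20, m = 40, seed = 21)
  ep <- sys$params
  xbar <- simulate_to_steady_state(ep, fast_config(), seed = 1)$xbar
  st <- stability_analysis(ep, xbar)

  b <- as.matrix(ep$beta)
  J <- matrix(0, 20, 20)
  for (i in 1:20) {
    u_i <- ep$alpha[i] + sum(b[, i] * xbar)
    for (j in 1:20) {
      J[i, j] <- b[j, i] * plogis(u_i) * (1 - plogis(u_i)) -
        (i == j) * ep$ell[i]
    }
  }
  expect_equal(st$J, J, tolerance = 1e-12)
  ev_o <- sort(Re(eigen(J, only.values = TRUE)$values))
  expect_equal(sort(Re(st$values)), ev_o, tolerance = 1e-10)
})

test_that("convergence protocol flags a non-converging oscillator", {
  # strong two-gene negative feedback loop with slow decay oscillates
  b <- matrix(0, 2, 2)
  b[1, 2] <- -60
  b[2, 1] <- 60
  ep <- expression_params(alpha = c(3, -3), ell = c(0.05, 0.05),
                          beta = b, s = 0, dt = 0.01)
  ss <- simulate_to_steady_state(ep, sim_config(burn_in = 1000,
                                                check_every = 500,
                                                t_max = 4000), seed = 1)
  st <- stability_analysis(ep, ss$xbar)
  # at least one of: protocol refuses to converge, or equilibrium unstable
  expect_true(!ss$converged || !st$stable)
})
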