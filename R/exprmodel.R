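#' Sample expression-model parameters for a network
#'
#' Draws the per-gene and per-edge parameters of the stochastic expression
#' model. Baseline synthesis offsets satisfy `sigmoid(alpha) ~ Beta(2, 8)`
#' (low but non-zero expression without regulation); decay rates are
#' `ell ~ Beta(8, 2)`, hard-clipped from below at `exp(-alpha)`. Because
#' `alpha` is almost surely negative, the clip usually binds, capping each
#' gene's maximum attainable expression `1/ell` at `exp(alpha)` (the odds of
#' its baseline activation) so steady-state expression cannot become
#' excessively large and the sigmoid input stays in its responsive range
#' even for densely regulated genes. Each regulator is an activator with probability
#' 0.8 (one sign per regulator, shared by all of its outgoing edges), and
#' each edge weight has magnitude `1 + |N(0, 1)|`, so `|beta| >= 1` on every
#' edge.
#'
#' @param graph A `grn_graph`.
#' @param seed Integer seed for parameter sampling.
#' @param s Global noise magnitude (default `1e-4`).
#' @param dt Euler-Maruyama step size (default `0.01`).
#' @return An object of class `grn_expression_params`: `alpha`, `ell`
#'   (length-`n` vectors), `beta` (sparse `n x n` matrix, `beta[j, i]` is the
#'   weight of edge `j -> i`), `s`, `dt`, `n`.
#' @export
#' @examples
#' g <- generate_network(graph_params(n = 50, k = 5, w = 9, p = 0.5,
#'                                    delta_in = 10, delta_out = 3, seed = 1))
#' ep <- sample_expression_params(g, seed = 2)
#' range(abs(ep$beta@x))  # all edge magnitudes >= 1
sample_expression_params <- function(graph, seed = 1L, s = 1e-4, dt = 0.01) {
  stopifnot(inherits(graph, "grn_graph"))
  n <- graph$n_nodes
  with_seed(seed, {
    sig_alpha <- rbeta(n, 2, 8)
    alpha <- qlogis(sig_alpha)
    ell <- rbeta(n, 8, 2)
    ell <- pmax(ell, exp(-alpha))
    activator <- runif(n) < 0.8
    sgn <- ifelse(activator, 1, -1)
    m <- nrow(graph$edges)
    if (m > 0) {
      mag <- 1 + abs(rnorm(m))
      beta <- Matrix::sparseMatrix(
        i = graph$edges[, 1], j = graph$edges[, 2],
        x = sgn[graph$edges[, 1]] * mag, dims = c(n, n))
    } else {
      beta <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                   x = numeric(0), dims = c(n, n))
    }
    structure(
      list(alpha = alpha, ell = ell, beta = methods::as(beta, "CsparseMatrix"),
           s = s, dt = dt, n = n),
      class = "grn_expression_params"
    )
  })
}

#' Construct expression parameters explicitly
#'
#' Low-level constructor for analyses and tests that need exact parameter
#' values rather than sampled ones.
#'
#' @param alpha,ell Per-gene synthesis offsets and decay rates.
#' @param beta Square regulator-by-target weight matrix (dense or sparse);
#'   `beta[j, i]` is the weight of edge `j -> i`.
#' @param s Noise magnitude.
#' @param dt Step size.
#' @return A `grn_expression_params` object.
#' @export
expression_params <- function(alpha, ell, beta, s = 1e-4, dt = 0.01) {
  n <- length(alpha)
  stopifnot(length(ell) == n, nrow(beta) == n, ncol(beta) == n,
            all(ell > 0), s >= 0, dt > 0)
  beta <- methods::as(methods::as(Matrix::Matrix(beta, sparse = TRUE),
                                  "generalMatrix"), "CsparseMatrix")
  structure(list(alpha = as.numeric(alpha), ell = as.numeric(ell),
                 beta = beta, s = s, dt = dt, n = n),
            class = "grn_expression_params")
}

#' @exportS3Method base::print
print.grn_expression_params <- function(x, ...) {
  cat(sprintf(
    "grn_expression_params: %d genes, %d edges, s=%g, dt=%g\n",
    x$n, length(x$beta@x), x$s, x$dt))
  invisible(x)
}

#' Simulation protocol settings
#'
#' Controls forward simulation to steady state: `burn_in` iterations are
#' discarded, then running means of expression are accumulated and compared
#' every `check_every` iterations; the system is declared converged when the
#' largest absolute log2 fold-change of the running means of genes expressed
#' above the noise floor falls below `tol`, up to a cap of `t_max`
#' iterations.
#'
#' @param burn_in Burn-in iterations (default 5000).
#' @param check_every Interval between convergence checks (default 1000).
#' @param t_max Iteration cap (default 20000).
#' @param tol Convergence threshold on the running-mean log2 fold-change
#'   (default `1e-3`).
#' @return An object of class `grn_sim_config`.
#' @export
sim_config <- function(burn_in = 5000L, check_every = 1000L,
                       t_max = 20000L, tol = 1e-3) {
  stopifnot_scalar(burn_in, "burn_in", lower = 0, integer = TRUE)
  stopifnot_scalar(check_every, "check_every", lower = 1, integer = TRUE)
  stopifnot_scalar(t_max, "t_max", lower = 1, integer = TRUE)
  stopifnot_scalar(tol, "tol", lower = 0, strict_lower = TRUE)
  if (burn_in >= t_max) stop("`burn_in` must be smaller than `t_max`", call. = FALSE)
  structure(list(burn_in = as.integer(burn_in),
                 check_every = as.integer(check_every),
                 t_max = as.integer(t_max), tol = tol),
            class = "grn_sim_config")
}

# Transposed weights (target x regulator) as dgCMatrix for the C++ core.
beta_transpose <- function(params) {
  methods::as(Matrix::t(params$beta), "CsparseMatrix")
}

#' Single Euler-Maruyama step (reference kernel)
#'
#' Pure-R reference implementation of the update rule
#' `x' = x + dt * (sigmoid(alpha + t(beta) %*% x) - ell * x) +
#' s * sqrt(dt) * sqrt(x) * z`, with the result floored at zero. The
#' compiled simulator advances the same recursion; this kernel exists for
#' clarity and for cross-checking.
#'
#' @param x Current state (non-negative, finite).
#' @param params A `grn_expression_params` object.
#' @param z Optional standard-normal vector; defaults to `rnorm(n)` (drawn
#'   from R's RNG). Ignored when `params$s == 0`.
#' @return The next state vector.
#' @export
step <- function(x, params, z = NULL) {
  stopifnot(inherits(params, "grn_expression_params"))
  if (!all(is.finite(x))) stop("non-finite input state", call. = FALSE)
  n <- params$n
  stopifnot(length(x) == n)
  u <- params$alpha + as.numeric(Matrix::crossprod(params$beta, x))
  drift <- plogis(u) - params$ell * x
  xp <- x + params$dt * drift
  if (params$s > 0) {
    if (is.null(z)) z <- rnorm(n)
    xp <- xp + params$s * sqrt(params$dt) * sqrt(pmax(x, 0)) * z
  }
  pmax(xp, 0)
}

#' Simulate to a steady state
#'
#' Runs the expression SDE from `init` (all genes silent by default) under
#' the running-mean convergence protocol of [sim_config()].
#'
#' @param params A `grn_expression_params` object.
#' @param config A [sim_config()] object.
#' @param seed Base seed for the simulation noise stream.
#' @param init Initial state (default: all zeros).
#' @param stream Stream index combined with `seed`; knockout `j` inside
#'   [knockout_screen()] runs on stream `j`, so a one-at-a-time run with the
#'   matching stream reproduces a screen column exactly.
#' @return An object of class `grn_steady_state`: `xbar` (post-burn-in
#'   running mean), `converged`, `iterations`, `expressed` (`xbar > s`) and
#'   the noise level `s`.
#' @export
simulate_to_steady_state <- function(params, config = sim_config(),
                                     seed = 1L, init = NULL, stream = 0) {
  stopifnot(inherits(params, "grn_expression_params"),
            inherits(config, "grn_sim_config"))
  if (is.null(init)) init <- numeric(params$n)
  if (!all(is.finite(init))) stop("non-finite initial state", call. = FALSE)
  res <- cpp_simulate(beta_transpose(params), params$alpha, params$ell,
                      params$s, params$dt, config$burn_in, config$check_every,
                      config$t_max, config$tol, init,
                      sanitize_seed(seed), stream, -1L)
  xbar <- as.numeric(res$xbar)
  structure(
    list(xbar = xbar, converged = res$converged,
         iterations = res$iterations, expressed = xbar > params$s,
         s = params$s),
    class = "grn_steady_state"
  )
}

#' @exportS3Method base::print
print.grn_steady_state <- function(x, ...) {
  cat(sprintf(
    "grn_steady_state: %d genes (%d expressed), %s after %d iterations\n",
    length(x$xbar), sum(x$expressed),
    if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' Residual of the deterministic fixed-point equation
#'
#' In the zero-noise limit any steady state satisfies
#' `x = sigmoid(alpha + t(beta) %*% x) / ell`; this returns the elementwise
#' residual `x - sigmoid(alpha + t(beta) %*% x) / ell`, a convergence
#' diagnostic.
#'
#' @param params A `grn_expression_params` object.
#' @param x State vector to evaluate.
#' @return Per-gene residuals.
#' @export
fixed_point_residual <- function(params, x) {
  u <- params$alpha + as.numeric(Matrix::crossprod(params$beta, x))
  x - plogis(u) / params$ell
}

#' Linear stability analysis at an equilibrium
#'
#' Builds the Jacobian of the deterministic part of the expression model at
#' `xbar`: `J[i, j] = beta[j, i] * sigmoid'(u_i) - (i == j) * ell_i` with
#' `u = alpha + t(beta) %*% xbar`, and inspects its eigenvalues. The
#' equilibrium is stable when every eigenvalue has negative real part.
#'
#' @param params A `grn_expression_params` object.
#' @param xbar (Approximate) equilibrium state.
#' @return A list with `values` (eigenvalues), `max_real`, `stable` and the
#'   Jacobian `J`.
#' @export
stability_analysis <- function(params, xbar) {
  u <- params$alpha + as.numeric(Matrix::crossprod(params$beta, xbar))
  sgp <- plogis(u) * (1 - plogis(u))
  J <- as.matrix(Matrix::t(params$beta)) * sgp  # row i scaled by sigmoid'(u_i)
  diag(J) <- diag(J) - params$ell
  ev <- eigen(J, only.values = TRUE)$values
  mr <- max(Re(ev))
  list(values = ev, max_real = mr, stable = mr < 0, J = J)
}
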