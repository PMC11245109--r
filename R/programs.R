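#' Specification of a mixed perturbed/unperturbed cell population
#'
#' Describes how to assemble a single-cell expression matrix mimicking a
#' pooled knockout experiment: a fraction of unperturbed ("baseline") cells
#' plus cells assigned uniformly at random to knockout conditions. Defaults
#' mirror a genome-scale pooled CRISPR experiment: 75,328 cells of which
#' roughly 8.1% are unperturbed, and an elevated noise level `s = 0.3` for
#' this analysis.
#'
#' @param n_cells Total number of cells.
#' @param baseline_fraction Fraction of unperturbed cells.
#' @param ko_conditions Gene indices available as knockout conditions
#'   (default `NULL` = all genes).
#' @param noise_s Expression noise used when sampling these cells.
#' @param seed RNG seed for condition assignment and simulation streams.
#' @return An object of class `grn_cell_population_spec`.
#' @export
cell_population_spec <- function(n_cells = 75328L, baseline_fraction = 0.081,
                                 ko_conditions = NULL, noise_s = 0.3,
                                 seed = 1L) {
  stopifnot_scalar(n_cells, "n_cells", lower = 1, integer = TRUE)
  stopifnot_scalar(baseline_fraction, "baseline_fraction", lower = 0, upper = 1)
  stopifnot_scalar(noise_s, "noise_s", lower = 0)
  structure(list(n_cells = as.integer(n_cells),
                 baseline_fraction = baseline_fraction,
                 ko_conditions = ko_conditions,
                 noise_s = noise_s, seed = as.integer(seed)),
            class = "grn_cell_population_spec")
}

#' Assemble a perturbed/unperturbed cell population
#'
#' Baseline cells are consecutive states of the SDE advanced from the
#' baseline steady state at noise `noise_s`. Each remaining cell is assigned
#' uniformly at random to a knockout condition; cells for a condition are
#' consecutive post-convergence states of the re-equilibrated knockout
#' dynamics (same burn-in/convergence protocol, per-condition noise
#' streams). No gene filtering is applied.
#'
#' @param params A `grn_expression_params` object (its `s` is overridden by
#'   `spec$noise_s` for this analysis).
#' @param baseline A `grn_steady_state`.
#' @param spec A [cell_population_spec()].
#' @param config [sim_config()] used for knockout re-equilibration.
#' @return A list of class `grn_cell_population`: `cells` (cell x gene) and
#'   `origin` (`"baseline"` or the knocked-out gene index, per cell).
#' @export
assemble_cells <- function(params, baseline, spec = cell_population_spec(),
                           config = sim_config()) {
  stopifnot(inherits(params, "grn_expression_params"),
            inherits(baseline, "grn_steady_state"),
            inherits(spec, "grn_cell_population_spec"))
  n <- params$n
  conds <- spec$ko_conditions %||% seq_len(n)
  n_base <- round(spec$n_cells * spec$baseline_fraction)
  n_pert <- spec$n_cells - n_base

  params$s <- spec$noise_s
  betaT <- beta_transpose(params)
  seed <- sanitize_seed(spec$seed)

  assignment <- if (n_pert > 0) {
    with_seed(spec$seed, sample(conds, n_pert, replace = TRUE))
  } else integer(0)
  counts <- table(assignment)

  cells <- matrix(NA_real_, nrow = spec$n_cells, ncol = n)
  origin <- character(spec$n_cells)
  row <- 0L

  if (n_base > 0) {
    m <- cpp_record_steps(betaT, params$alpha, params$ell, params$s,
                          params$dt, baseline$xbar, n_base, seed, n, -1L)
    cells[seq_len(n_base), ] <- t(m)
    origin[seq_len(n_base)] <- "baseline"
    row <- n_base
  }

  for (cond in names(counts)) {
    j <- as.integer(cond)
    cnt <- as.integer(counts[[cond]])
    res <- cpp_equilibrate_record(betaT, params$alpha, params$ell, params$s,
                                  params$dt, config$burn_in,
                                  config$check_every, config$t_max,
                                  config$tol, baseline$xbar, seed,
                                  j - 1L, j - 1L, cnt)
    cells[row + seq_len(cnt), ] <- t(res$cells)
    origin[row + seq_len(cnt)] <- as.character(j)
    row <- row + cnt
  }

  structure(list(cells = cells, origin = origin, spec = spec),
            class = "grn_cell_population")
}

#' Normalise genes to zero mean and unit variance
#'
#' @param matrix Cell-by-gene matrix with at least two rows.
#' @return Matrix of the same shape; genes with zero variance map to
#'   all-zero columns.
#' @export
znormalize <- function(matrix) {
  m <- as.matrix(matrix)
  if (nrow(m) < 2) stop("need at least 2 cells", call. = FALSE)
  mu <- colMeans(m)
  sdev <- apply(m, 2, sd)
  out <- sweep(m, 2, mu, "-")
  nz <- sdev > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2, sdev[nz], "/")
  out[, !nz] <- 0
  out
}

#' Truncated singular value decomposition
#'
#' Top-`n_components` singular triplets of a (typically z-normalised)
#' cell-by-gene matrix, computed with LAPACK via [base::svd()] and
#' truncated; `U %*% diag(S) %*% t(V)` is the best rank-k approximation.
#'
#' @param matrix Input matrix.
#' @param n_components Number of components (<= `min(dim(matrix))`).
#' @return List with `u` (cells x k), `d` (singular values, non-increasing)
#'   and `v` (genes x k).
#' @export
truncated_svd <- function(matrix, n_components = 200L) {
  m <- as.matrix(matrix)
  k <- as.integer(n_components)
  if (k < 1 || k > min(dim(m)))
    stop("`n_components` must be between 1 and min(dim(matrix))", call. = FALSE)
  s <- svd(m, nu = k, nv = k)
  list(u = s$u, d = s$d[seq_len(k)], v = s$v)
}

#' Define gene programs from singular vectors
#'
#' Each program corresponds one-to-one with a gene singular vector and is
#' the set of `program_size` genes with the largest squared loadings on it
#' (ties broken by gene index). Programs from different components may
#' overlap.
#'
#' @param v Gene-by-component loading matrix, or the result of
#'   [truncated_svd()].
#' @param program_size Genes per program (default 100; capped at the number
#'   of genes).
#' @return An object of class `grn_program_set`: `v`, `programs` (list of
#'   integer gene-index vectors) and `program_size`.
#' @export
define_programs <- function(v, program_size = 100L) {
  if (is.list(v) && !is.null(v$v)) v <- v$v
  v <- as.matrix(v)
  size <- min(as.integer(program_size), nrow(v))
  programs <- lapply(seq_len(ncol(v)), function(j) {
    ord <- order(-v[, j]^2, seq_len(nrow(v)))
    sort(ord[seq_len(size)])
  })
  structure(list(v = v, programs = programs, program_size = size),
            class = "grn_program_set")
}

#' @exportS3Method base::print
print.grn_program_set <- function(x, ...) {
  cat(sprintf("grn_program_set: %d programs of %d genes (from %d genes)\n",
              length(x$programs), x$program_size, nrow(x$v)))
  invisible(x)
}

#' Maximum program overlap against another program set
#'
#' For each reference program, the largest number of shared genes with any
#' program of the other set (counts, not Jaccard).
#'
#' @param reference,other `grn_program_set` objects over the same gene
#'   universe.
#' @return Integer vector, one maximum overlap count per reference program.
#' @export
program_overlap <- function(reference, other) {
  stopifnot(inherits(reference, "grn_program_set"),
            inherits(other, "grn_program_set"),
            nrow(reference$v) == nrow(other$v))
  n_genes <- nrow(reference$v)
  memb <- function(ps) {
    m <- matrix(FALSE, n_genes, length(ps$programs))
    for (j in seq_along(ps$programs)) m[ps$programs[[j]], j] <- TRUE
    m
  }
  counts <- crossprod(memb(reference), memb(other))  # ref x other overlaps
  as.integer(apply(counts, 1, max))
}

#' Canonical correlations between two loading matrices
#'
#' Orthonormalises both gene-by-component loading matrices and returns the
#' singular values of their cross-product - the canonical correlations
#' between the two low-rank representations. For orthonormal inputs (as
#' produced by [truncated_svd()]) this is exactly the SVD of `t(V) %*% V'`.
#'
#' @param v,v_prime Gene-by-component matrices over the same genes.
#' @return Non-increasing canonical correlations in `[0, 1]`, of length
#'   `min(ncol(v), ncol(v_prime))`.
#' @export
cca <- function(v, v_prime) {
  v <- as.matrix(v); v_prime <- as.matrix(v_prime)
  if (nrow(v) != nrow(v_prime))
    stop("inputs must share the gene dimension", call. = FALSE)
  qa <- qr.Q(qr(v))
  qb <- qr.Q(qr(v_prime))
  d <- svd(crossprod(qa, qb), nu = 0, nv = 0)$d
  pmin(pmax(d, 0), 1)
}
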