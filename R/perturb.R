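#' Knock out a gene
#'
#' Returns a copy of the expression parameters with gene `j`'s outgoing
#' regulatory effects nullified (row `j` of `beta` zeroed). All other
#' parameters are untouched.
#'
#' @param params A `grn_expression_params` object.
#' @param j Gene index (1-based).
#' @return A modified copy of `params`.
#' @export
knockout <- function(params, j) {
  stopifnot(inherits(params, "grn_expression_params"))
  stopifnot_scalar(j, "j", lower = 1, upper = params$n, integer = TRUE)
  beta <- params$beta
  beta[j, ] <- 0
  params$beta <- methods::as(Matrix::drop0(beta), "CsparseMatrix")
  params
}

#' Systematic knockout screen
#'
#' Knocks out each gene in turn, re-equilibrates the system from the
#' baseline steady state under the same burn-in/convergence protocol, and
#' records the log2 fold-change of every other gene's steady-state
#' expression: `log2fc[j, i] = log2(xbar_i | KO j) - log2(xbar_i)`.
#' Knockout `j` runs on noise stream `j` derived from `seed`, so a screen is
#' identical to gene-by-gene [simulate_to_steady_state()] runs with matching
#' streams.
#'
#' @param params A `grn_expression_params` object.
#' @param baseline Baseline `grn_steady_state` (its `xbar` is the starting
#'   state for every knockout).
#' @param config A [sim_config()].
#' @param seed Base seed for the per-knockout noise streams.
#' @return An object of class `grn_screen`: `log2fc` (`n x n`, row `j` =
#'   effects of knocking out `j`, diagonal `NA`), `baseline`, `expressed`
#'   (baseline `xbar > s`), `converged_per_ko`, `iterations_per_ko`, `seed`.
#'   Post-knockout means are floored at machine epsilon before taking logs;
#'   downstream summaries only use genes expressed at baseline.
#' @export
knockout_screen <- function(params, baseline, config = sim_config(), seed = 1L) {
  stopifnot(inherits(params, "grn_expression_params"),
            inherits(baseline, "grn_steady_state"))
  if (!baseline$converged)
    warning("baseline steady state is flagged as not converged")
  res <- cpp_screen(beta_transpose(params), params$alpha, params$ell,
                    params$s, params$dt, config$burn_in, config$check_every,
                    config$t_max, config$tol, baseline$xbar,
                    sanitize_seed(seed))
  eps <- .Machine$double.eps
  base_log <- log2(pmax(baseline$xbar, eps))
  # column j of xbar_ko is the steady state under KO j -> transpose so that
  # row j holds the effects of knocking out j
  log2fc <- t(log2(pmax(res$xbar_ko, eps)) - base_log)
  diag(log2fc) <- NA_real_
  structure(
    list(log2fc = log2fc, baseline = baseline,
         expressed = baseline$expressed,
         converged_per_ko = as.logical(res$converged),
         iterations_per_ko = as.integer(res$iterations),
         seed = seed),
    class = "grn_screen"
  )
}

#' @exportS3Method base::print
print.grn_screen <- function(x, ...) {
  cat(sprintf(
    "grn_screen: %d knockouts, %d genes expressed at baseline, %d/%d converged\n",
    nrow(x$log2fc), sum(x$expressed), sum(x$converged_per_ko),
    length(x$converged_per_ko)))
  invisible(x)
}

# Absolute effects restricted to expressed-by-expressed ordered pairs,
# diagonal excluded (NA).
screen_effect_matrix <- function(screen) {
  stopifnot(inherits(screen, "grn_screen"))
  idx <- which(screen$expressed)
  abs(screen$log2fc[idx, idx, drop = FALSE])
}

#' Hub knockout and hub target counts
#'
#' A gene is a *hub KO* if knocking it out changes at least `count_thresh`
#' other expressed genes by more than `effect_thresh` in absolute log2
#' fold-change; a *hub target* is changed by at least `count_thresh`
#' knockouts at the same threshold. Genes below the noise floor at baseline
#' are excluded from both roles.
#'
#' @param screen A `grn_screen`, or a plain log2 fold-change matrix (rows =
#'   knockouts) for constructed inputs.
#' @param effect_thresh Absolute log2 fold-change threshold (default 0.1).
#' @param count_thresh Minimum number of affected genes / affecting
#'   knockouts (default 100).
#' @param expressed Logical mask used when `screen` is a plain matrix
#'   (default: all genes).
#' @return A list of class `grn_hub_summary`: `n_hub_ko`, `n_hub_target`,
#'   the thresholds and the number of analyzed genes.
#' @export
hub_counts <- function(screen, effect_thresh = 0.1, count_thresh = 100,
                       expressed = NULL) {
  if (inherits(screen, "grn_screen")) {
    m <- screen_effect_matrix(screen)
  } else {
    lf <- as.matrix(screen)
    if (is.null(expressed)) expressed <- rep(TRUE, nrow(lf))
    idx <- which(expressed)
    m <- abs(lf[idx, idx, drop = FALSE])
    diag(m) <- NA_real_
  }
  n_hub_ko <- sum(rowSums(m > effect_thresh, na.rm = TRUE) >= count_thresh)
  n_hub_target <- sum(colSums(m > effect_thresh, na.rm = TRUE) >= count_thresh)
  structure(
    list(n_hub_ko = n_hub_ko, n_hub_target = n_hub_target,
         effect_thresh = effect_thresh, count_thresh = count_thresh,
         n_analyzed = nrow(m)),
    class = "grn_hub_summary"
  )
}

#' @exportS3Method base::print
print.grn_hub_summary <- function(x, ...) {
  cat(sprintf(
    "hub KOs: %d | hub targets: %d (|log2FC| > %g in >= %d of %d genes)\n",
    x$n_hub_ko, x$n_hub_target, x$effect_thresh, x$count_thresh, x$n_analyzed))
  invisible(x)
}

#' Stratify knockout effects by network distance and group
#'
#' Partitions ordered expressed-gene pairs `(j, i)`, `j != i`, by the
#' directed shortest-path distance from `j` to `i` (direct = distance 1,
#' mediated = everything else, including unreachable pairs) and by whether
#' the two genes share a group, and summarises the absolute effect
#' distribution of each stratum.
#'
#' @param screen A `grn_screen`.
#' @param distances Matrix from [shortest_path_distances()] on the same
#'   network.
#' @param group Per-gene group labels from the same network.
#' @param effect_thresh Threshold used for the exceedance fractions
#'   (default 0.01).
#' @return A list with per-distance effect vectors and exceedance fractions,
#'   within-/across-group effect vectors and fractions, and a direct /
#'   mediated split (effects, exceedance fractions, pair counts).
#' @export
stratify_effects <- function(screen, distances, group, effect_thresh = 0.01) {
  stopifnot(inherits(screen, "grn_screen"),
            nrow(distances) == nrow(screen$log2fc),
            length(group) == nrow(screen$log2fc))
  idx <- which(screen$expressed)
  eff <- abs(screen$log2fc[idx, idx, drop = FALSE])
  d <- distances[idx, idx, drop = FALSE]
  g <- group[idx]
  off <- !diag(TRUE, length(idx))  # ordered pairs, self excluded

  effv <- eff[off]
  dv <- d[off]
  same <- outer(g, g, "==")[off]

  dlev <- sort(unique(dv))
  by_dist <- split(effv, factor(dv, levels = dlev))
  exceed <- vapply(by_dist, function(v) mean(v > effect_thresh), numeric(1))

  direct <- dv == 1
  list(
    distance_levels = dlev,
    effects_by_distance = by_dist,
    exceed_by_distance = exceed,
    within = effv[same],
    across = effv[!same],
    within_exceed = mean(effv[same] > effect_thresh),
    across_exceed = mean(effv[!same] > effect_thresh),
    direct = effv[direct],
    mediated = effv[!direct],
    direct_exceed = mean(effv[direct] > effect_thresh),
    mediated_exceed = mean(effv[!direct] > effect_thresh),
    n_pairs = length(effv),
    effect_thresh = effect_thresh
  )
}

#' Sample steady-state cells from the baseline condition
#'
#' Advances the SDE from the baseline steady state and records the state at
#' every forward step as one "cell".
#'
#' @param params A `grn_expression_params` object.
#' @param baseline A `grn_steady_state`.
#' @param n_steps Number of forward steps = number of cells (default 10000).
#' @param seed Noise-stream seed.
#' @return A list of class `grn_cells` with `cells` (cell-by-gene matrix; no
#'   gene filtering) and `origin` (condition label per cell).
#' @export
sample_cells <- function(params, baseline, n_steps = 10000L, seed = 1L) {
  stopifnot(inherits(params, "grn_expression_params"),
            inherits(baseline, "grn_steady_state"))
  stopifnot_scalar(n_steps, "n_steps", lower = 1, integer = TRUE)
  m <- cpp_record_steps(beta_transpose(params), params$alpha, params$ell,
                        params$s, params$dt, baseline$xbar,
                        as.integer(n_steps), sanitize_seed(seed), 0, -1L)
  structure(
    list(cells = t(m), origin = rep("baseline", n_steps)),
    class = "grn_cells"
  )
}

#' Pairwise gene coexpression across cells
#'
#' @param sample A `grn_cells` object (or a plain cell-by-gene matrix) with
#'   at least two cells.
#' @return Symmetric Pearson correlation matrix; genes with zero variance
#'   across cells yield `NA` entries.
#' @export
coexpression <- function(sample) {
  cells <- if (inherits(sample, "grn_cells")) sample$cells else as.matrix(sample)
  if (nrow(cells) < 2) stop("need at least 2 cells", call. = FALSE)
  suppressWarnings(cor(cells))
}
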