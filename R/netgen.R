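#' Parameters for the network generating algorithm
#'
#' Bundles the six knobs of the group-structured preferential-attachment
#' generator together with an RNG seed.
#'
#' @param n Number of genes (nodes) in the finished network.
#' @param k Number of gene groups; each node belongs to exactly one group.
#' @param w Within-group affinity. When an attachment endpoint is drawn, the
#'   weight of candidates in the anchor's group is multiplied by `w`; `w = 1`
#'   (or `k = 1`) dissolves group structure and recovers the classic directed
#'   preferential-attachment model. Roughly a fraction `w / (w + k - 1)` of
#'   edges land within groups.
#' @param p Probability that a growth step adds a new node (with one incoming
#'   edge) rather than an edge between existing nodes. The mean number of
#'   regulators per gene is approximately `1 / p`.
#' @param delta_in,delta_out Uniformity offsets added to the in-/out-degree
#'   when drawing attachment targets/sources. Small values produce
#'   heavy-tailed (hub-rich) degree distributions; large values flatten them.
#' @param seed Integer seed; the generator is fully reproducible given
#'   `params`.
#'
#' @return An object of class `grn_graph_params`.
#' @seealso [generate_network()], [parameter_grid()]
#' @export
#' @examples
#' gp <- graph_params(n = 100, k = 5, w = 9, p = 0.5,
#'                    delta_in = 10, delta_out = 1, seed = 1)
#' g <- generate_network(gp)
#' degree_summary(g)
graph_params <- function(n, k = 1L, w = 1, p = 0.5,
                         delta_in = 1, delta_out = 1, seed = 1L) {
  stopifnot_scalar(n, "n", lower = 1, integer = TRUE)
  stopifnot_scalar(k, "k", lower = 1, upper = n, integer = TRUE)
  stopifnot_scalar(w, "w", lower = 1)
  stopifnot_scalar(p, "p", lower = 0, upper = 1, strict_lower = TRUE)
  stopifnot_scalar(delta_in, "delta_in", lower = 0, strict_lower = TRUE)
  stopifnot_scalar(delta_out, "delta_out", lower = 0, strict_lower = TRUE)
  stopifnot_scalar(seed, "seed", integer = TRUE)
  structure(
    list(n = as.integer(n), k = as.integer(k), w = w, p = p,
         delta_in = delta_in, delta_out = delta_out, seed = as.integer(seed)),
    class = "grn_graph_params"
  )
}

#' @exportS3Method base::print
print.grn_graph_params <- function(x, ...) {
  cat(sprintf(
    "grn_graph_params: n=%d k=%d w=%g p=%g delta_in=%g delta_out=%g seed=%d\n",
    x$n, x$k, x$w, x$p, x$delta_in, x$delta_out, x$seed))
  invisible(x)
}

#' Generate a group-structured directed scale-free network
#'
#' Grows a directed network by preferential attachment. The seed graph
#' consists of `k` isolated nodes, one per group. Each growth step adds,
#' with probability `p`, a new node (assigned to a uniform-random group)
#' receiving one incoming edge from an existing node; otherwise it adds a
#' directed edge between two existing nodes. Sources are drawn with weight
#' proportional to `out_degree + delta_out` and targets with weight
#' proportional to `in_degree + delta_in`; the weight of candidates in the
#' same group as the anchor endpoint (the new node, or the already-chosen
#' source) is further multiplied by `w`. Self-loops and duplicate edges are
#' rejected: the endpoint is resampled up to 100 times, then the whole
#' growth event is resampled. Growth stops when the node count reaches `n`.
#'
#' @param params A [graph_params()] object.
#' @return An object of class `grn_graph` with elements `n_nodes`, `edges`
#'   (two-column integer matrix, rows are `source -> target`, 1-based),
#'   `group` (integer vector in `1..k`), `in_degree`, `out_degree`, `k`, and
#'   the generating `params`.
#' @export
generate_network <- function(params) {
  if (!inherits(params, "grn_graph_params"))
    stop("`params` must be created by graph_params()", call. = FALSE)
  n <- params$n; k <- params$k; w <- params$w; p <- params$p
  d_in <- params$delta_in; d_out <- params$delta_out

  with_seed(params$seed, {
    group <- integer(n)
    group[seq_len(k)] <- seq_len(k)   # seed graph: one isolated node per group
    in_deg <- numeric(n)
    out_deg <- numeric(n)
    cap <- max(16L, ceiling((n - k + 1) / p * 1.3))
    e_src <- integer(cap); e_tgt <- integer(cap)
    n_edges <- 0L
    seen <- new.env(hash = TRUE, parent = emptyenv())  # duplicate-edge index
    n_cur <- k
    event_failures <- 0L

    add_edge <- function(s, t) {
      n_edges <<- n_edges + 1L
      if (n_edges > length(e_src)) {
        e_src <<- c(e_src, integer(length(e_src)))
        e_tgt <<- c(e_tgt, integer(length(e_tgt)))
      }
      e_src[n_edges] <<- s
      e_tgt[n_edges] <<- t
      out_deg[s] <<- out_deg[s] + 1
      in_deg[t] <<- in_deg[t] + 1
      assign(paste0(s, "|", t), TRUE, envir = seen)
    }

    while (n_cur < n) {
      if (runif(1) < p) {
        # node event: new node is the target; source drawn with affinity to
        # the new node's group
        v <- n_cur + 1L
        g <- sample.int(k, 1L)
        group[v] <- g
        idx <- seq_len(n_cur)
        wt <- (out_deg[idx] + d_out) * ((group[idx] == g) * (w - 1) + 1)
        s <- sample.int(n_cur, 1L, prob = wt)
        n_cur <- v
        add_edge(s, v)
        event_failures <- 0L
      } else {
        # edge event: source drawn by out-degree alone, target with affinity
        # to the source's group
        if (n_cur < 2L) {
          event_failures <- event_failures + 1L
          if (event_failures > 1000L)
            stop("edge sampling saturated: retry budget exceeded", call. = FALSE)
          next
        }
        idx <- seq_len(n_cur)
        s <- sample.int(n_cur, 1L, prob = out_deg[idx] + d_out)
        wt <- (in_deg[idx] + d_in) * ((group[idx] == group[s]) * (w - 1) + 1)
        placed <- FALSE
        for (try in seq_len(100L)) {
          t_ <- sample.int(n_cur, 1L, prob = wt)
          if (t_ != s && !exists(paste0(s, "|", t_), envir = seen, inherits = FALSE)) {
            add_edge(s, t_)
            placed <- TRUE
            break
          }
        }
        if (placed) {
          event_failures <- 0L
        } else {
          event_failures <- event_failures + 1L
          if (event_failures > 1000L)
            stop("edge sampling saturated: retry budget exceeded (dense regime)",
                 call. = FALSE)
        }
      }
    }

    structure(
      list(n_nodes = n,
           edges = cbind(source = e_src[seq_len(n_edges)],
                         target = e_tgt[seq_len(n_edges)]),
           group = group,
           k = k,
           in_degree = in_deg,
           out_degree = out_deg,
           params = params),
      class = "grn_graph"
    )
  })
}

#' Construct a network object from an explicit edge list
#'
#' Mainly useful for building small fixed topologies (chains, cycles, toy
#' motifs) in analyses and tests.
#'
#' @param n Number of nodes.
#' @param edges Two-column matrix (source, target), 1-based; may have zero
#'   rows.
#' @param group Integer group label per node (default: all in group 1).
#' @return A `grn_graph`.
#' @export
as_grn_graph <- function(n, edges, group = rep(1L, n)) {
  edges <- matrix(as.integer(edges), ncol = 2,
                  dimnames = list(NULL, c("source", "target")))
  if (nrow(edges) > 0) {
    if (any(edges < 1L | edges > n)) stop("edge endpoints out of range")
    if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed")
    if (anyDuplicated(paste(edges[, 1], edges[, 2])))
      stop("duplicate edges are not allowed")
  }
  if (length(group) != n) stop("`group` must have one label per node")
  group <- as.integer(factor(group, levels = sort(unique(group))))
  structure(
    list(n_nodes = as.integer(n),
         edges = edges,
         group = group,
         k = max(group),
         in_degree = tabulate(edges[, 2], nbins = n),
         out_degree = tabulate(edges[, 1], nbins = n),
         params = NULL),
    class = "grn_graph"
  )
}

#' @exportS3Method base::print
print.grn_graph <- function(x, ...) {
  cat(sprintf("grn_graph: %d nodes, %d edges, %d groups\n",
              x$n_nodes, nrow(x$edges), x$k))
  invisible(x)
}

# Internal invariant check used by tests.
validate_grn_graph <- function(g) {
  stopifnot(
    inherits(g, "grn_graph"),
    nrow(g$edges) == 0 || all(g$edges[, 1] != g$edges[, 2]),
    !anyDuplicated(paste(g$edges[, 1], g$edges[, 2])),
    all(g$in_degree == tabulate(g$edges[, 2], nbins = g$n_nodes)),
    all(g$out_degree == tabulate(g$edges[, 1], nbins = g$n_nodes)),
    all(g$group >= 1L & g$group <= g$k)
  )
  invisible(TRUE)
}

#' Structural summary of a generated network
#'
#' @param graph A `grn_graph`.
#' @return A list of class `grn_degree_summary` with `mean_in_degree`,
#'   `cv_in`, `cv_out` (coefficient of variation, sd/mean, of the in- and
#'   out-degree distributions) and `within_group_fraction` (fraction of edges
#'   whose endpoints share a group). A graph without edges has undefined
#'   CVs: they are returned as `NA` with `degenerate = TRUE` and a warning.
#' @export
degree_summary <- function(graph) {
  stopifnot(inherits(graph, "grn_graph"))
  if (graph$n_nodes < 1L) stop("empty graph", call. = FALSE)
  m <- nrow(graph$edges)
  if (m == 0L) {
    warning("graph has no edges; degree CVs are undefined")
    return(structure(list(mean_in_degree = 0, cv_in = NA_real_,
                          cv_out = NA_real_,
                          within_group_fraction = NA_real_,
                          degenerate = TRUE),
                     class = "grn_degree_summary"))
  }
  cv <- function(d) sd(d) / mean(d)
  wg <- mean(graph$group[graph$edges[, 1]] == graph$group[graph$edges[, 2]])
  structure(
    list(mean_in_degree = mean(graph$in_degree),
         cv_in = cv(graph$in_degree),
         cv_out = cv(graph$out_degree),
         within_group_fraction = wg,
         degenerate = FALSE),
    class = "grn_degree_summary"
  )
}

#' @exportS3Method base::print
print.grn_degree_summary <- function(x, ...) {
  cat(sprintf(
    "mean in-degree %.3f | CV(in) %.3f | CV(out) %.3f | within-group %.3f\n",
    x$mean_in_degree, x$cv_in, x$cv_out, x$within_group_fraction))
  invisible(x)
}

#' Directed shortest-path distance matrix
#'
#' Distances follow edge direction (regulator to target); unreachable pairs
#' are `Inf` and the diagonal is 0.
#'
#' @param graph A `grn_graph`.
#' @return An `n x n` numeric matrix of path lengths.
#' @export
shortest_path_distances <- function(graph) {
  stopifnot(inherits(graph, "grn_graph"))
  ig <- igraph::make_empty_graph(n = graph$n_nodes, directed = TRUE)
  if (nrow(graph$edges) > 0)
    ig <- igraph::add_edges(ig, t(graph$edges))
  d <- igraph::distances(ig, mode = "out", algorithm = "unweighted")
  dimnames(d) <- NULL
  d
}

#' Full factorial grid of generating parameters
#'
#' Enumerates every combination of the study's generator settings:
#' `p` in 1/2, 1/4, 1/8, 1/16; `k` in 1, 5, 10, 50, 100; `w` in 1, 9, 40,
#' 90, 400, 900; `delta_in` in 10, 30, 100, 300; `delta_out` in 1, 3, 10,
#' 30 - a 4 x 5 x 6 x 4 x 4 = 1920-row grid.
#'
#' @param n Node count attached to every combination (default 2000).
#' @return A data frame with columns `n`, `p`, `k`, `w`, `delta_in`,
#'   `delta_out`, one row per combination. Use [as_graph_params()] to turn a
#'   row into a [graph_params()] object.
#' @export
parameter_grid <- function(n = 2000L) {
  g <- expand.grid(p = c(1 / 2, 1 / 4, 1 / 8, 1 / 16),
                   k = c(1L, 5L, 10L, 50L, 100L),
                   w = c(1, 9, 40, 90, 400, 900),
                   delta_in = c(10, 30, 100, 300),
                   delta_out = c(1, 3, 10, 30),
                   KEEP.OUT.ATTRS = FALSE)
  cbind(n = as.integer(n), g)
}

#' Convert a parameter-grid row to graph parameters
#'
#' @param row A single-row data frame (or list) with fields `n`, `p`, `k`,
#'   `w`, `delta_in`, `delta_out`.
#' @param seed RNG seed for the resulting [graph_params()].
#' @return A `grn_graph_params` object.
#' @export
as_graph_params <- function(row, seed = 1L) {
  graph_params(n = row$n, k = row$k, w = row$w, p = row$p,
               delta_in = row$delta_in, delta_out = row$delta_out, seed = seed)
}
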