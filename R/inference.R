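#' Pairwise summary table over ordered gene pairs
#'
#' Joins, for every ordered pair `(from, to)` with `from != to`, the ground
#' truth (edge indicator and absolute edge weight), the absolute knockout
#' effect, the coexpression value and the directed network distance.
#'
#' @param graph A `grn_graph`.
#' @param params Matching `grn_expression_params`.
#' @param screen Matching `grn_screen`.
#' @param coexpr Gene-by-gene correlation matrix from [coexpression()].
#' @param distances Optional distance matrix; computed from `graph` when
#'   omitted.
#' @return A data frame with one row per ordered pair: `from`, `to`,
#'   `has_edge`, `weight`, `log2fc` (absolute), `coexpression`, `distance`.
#' @export
build_pair_table <- function(graph, params, screen, coexpr,
                             distances = NULL) {
  stopifnot(inherits(graph, "grn_graph"),
            inherits(params, "grn_expression_params"),
            inherits(screen, "grn_screen"))
  n <- graph$n_nodes
  if (params$n != n || nrow(screen$log2fc) != n ||
      nrow(coexpr) != n || ncol(coexpr) != n)
    stop("inputs describe different networks (size mismatch)", call. = FALSE)
  if (is.null(distances)) distances <- shortest_path_distances(graph)

  from <- rep(seq_len(n), times = n)
  to <- rep(seq_len(n), each = n)
  keep <- from != to
  from <- from[keep]; to <- to[keep]
  idx <- cbind(from, to)

  bmat <- as.matrix(params$beta)
  data.frame(
    from = from,
    to = to,
    has_edge = bmat[idx] != 0,
    weight = abs(bmat[idx]),
    log2fc = abs(screen$log2fc[idx]),
    coexpression = coexpr[idx],
    distance = distances[idx]
  )
}

#' Enrichment of true edges among top-ranked pairs
#'
#' Ratio of the edge fraction among the top `top_quantile` of pairs ranked
#' by a summary statistic to the overall edge fraction; 1 means no
#' enrichment.
#'
#' @param table Data frame from [build_pair_table()].
#' @param statistic Column to rank by: `"log2fc"` or `"coexpression"`
#'   (absolute value is used), or any numeric column name.
#' @param top_quantile Fraction of pairs taken as the top set.
#' @return The enrichment ratio (single number).
#' @export
edge_enrichment <- function(table, statistic = c("log2fc", "coexpression"),
                            top_quantile = 0.05) {
  statistic <- statistic[1]
  if (!statistic %in% names(table))
    stop(sprintf("no column '%s' in the pair table", statistic), call. = FALSE)
  stopifnot_scalar(top_quantile, "top_quantile", lower = 0, upper = 1,
                   strict_lower = TRUE)
  stat <- abs(table[[statistic]])
  n_top <- ceiling(top_quantile * nrow(table))
  if (n_top < 1) stop("empty top quantile", call. = FALSE)
  top <- order(-stat, seq_along(stat))[seq_len(n_top)]
  mean(table$has_edge[top]) / mean(table$has_edge)
}

#' Rank correlations between pairwise statistics
#'
#' Spearman correlations of the knockout effect and coexpression magnitude
#' with the true edge weight (on edge pairs), and of coexpression with
#' knockout effects (over all pairs and on edge pairs).
#'
#' @param table Data frame from [build_pair_table()].
#' @return List with `effect_vs_weight`, `coexpr_vs_weight`,
#'   `coexpr_vs_effect_all`, `coexpr_vs_effect_edges`.
#' @export
rank_correlations <- function(table) {
  e <- table[table$has_edge, , drop = FALSE]
  if (nrow(e) < 2) stop("fewer than 2 edge pairs", call. = FALSE)
  sp <- function(x, y) cor(x, y, method = "spearman")
  list(
    effect_vs_weight = sp(e$log2fc, e$weight),
    coexpr_vs_weight = sp(abs(e$coexpression), e$weight),
    coexpr_vs_effect_all = sp(abs(table$coexpression), table$log2fc),
    coexpr_vs_effect_edges = sp(abs(e$coexpression), e$log2fc)
  )
}

#' Regress logit hub fractions on generating parameters
#'
#' Ordinary least squares of the logit-transformed fraction of analyzed
#' genes that are hub KOs (or hub targets) on the generator knobs:
#' `logit(fraction) ~ 1 + 1/p + k' + w + delta_in + delta_out`, where
#' `k' = n` for single-group networks (`k = 1` dissolves group structure,
#' which is equivalent to every gene having its own group). Boundary
#' fractions are handled with the empirical-logit correction
#' `(count + 0.5) / (n + 1)`.
#'
#' @param summaries Data frame with one row per network and columns `p`,
#'   `k`, `w`, `delta_in`, `delta_out`, `n` (genes in the network),
#'   `n_expressed` (analyzed genes) and the hub counts named by `response`.
#' @param response Column with the hub counts, e.g. `"n_hub_ko"` or
#'   `"n_hub_target"`.
#' @return A list of class `grn_regression_report`: `coefficients`,
#'   `p_values`, `r_squared`, `response`, and the fitted `model`.
#' @export
hub_fraction_regression <- function(summaries, response = "n_hub_ko") {
  need <- c("p", "k", "w", "delta_in", "delta_out", "n", "n_expressed", response)
  miss <- setdiff(need, names(summaries))
  if (length(miss) > 0)
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  df <- data.frame(
    y = qlogis((summaries[[response]] + 0.5) / (summaries$n_expressed + 1)),
    inv_p = 1 / summaries$p,
    k_prime = ifelse(summaries$k == 1, summaries$n, summaries$k),
    w = summaries$w,
    delta_in = summaries$delta_in,
    delta_out = summaries$delta_out
  )
  fit <- lm(y ~ inv_p + k_prime + w + delta_in + delta_out, data = df)
  sm <- summary(fit)
  structure(
    list(coefficients = coef(fit),
         p_values = sm$coefficients[, "Pr(>|t|)"],
         r_squared = sm$r.squared,
         response = response,
         model = fit),
    class = "grn_regression_report"
  )
}

#' @exportS3Method base::print
print.grn_regression_report <- function(x, ...) {
  cat(sprintf("hub-fraction regression (%s), r^2 = %.3f\n",
              x$response, x$r_squared))
  print(round(cbind(estimate = x$coefficients, p = x$p_values), 4))
  invisible(x)
}
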