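#' Load a pairwise perturbation-by-gene p-value table
#'
#' Reads a (gzip-compressed) CSV of FDR-corrected per-pair p-values with
#' perturbations as rows and measured genes as columns, both identified by
#' ENSEMBL gene IDs (first column = the perturbation's target gene ID). The
#' table is restricted to perturbations whose target gene is itself among
#' the measured columns; when several perturbations hit the same gene, the
#' one with a significant effect on its own target transcript (p <
#' `self_alpha`) is kept, falling back to the first listed. Expression-level
#' filtering is assumed to have been applied upstream by the data provider.
#'
#' @param path Path to the CSV (plain or `.gz`).
#' @param self_alpha Significance level used to arbitrate duplicate
#'   perturbations of the same target (default 0.05).
#' @return A numeric matrix (perturbation target ID x measured gene ID) with
#'   attributes `n_dropped_unmatched` and `n_dropped_duplicates`. If no row
#'   matches, an empty matrix is returned with a warning.
#' @export
load_pairwise_pvalues <- function(path, self_alpha = 0.05) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop(errorCondition(
      sprintf("external data unavailable: '%s' not found", path),
      class = c("grnforge_external_data_unavailable", "error", "condition")))
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  tab <- read.csv(con, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids

  matched <- ids %in% colnames(m)
  n_unmatched <- sum(!matched)
  m <- m[matched, , drop = FALSE]
  ids <- ids[matched]
  if (nrow(m) == 0) {
    warning("no perturbations matched a measured gene; returning empty table")
    return(structure(m, n_dropped_unmatched = n_unmatched,
                     n_dropped_duplicates = 0L))
  }

  keep <- rep(TRUE, nrow(m))
  dup_ids <- unique(ids[duplicated(ids)])
  for (id in dup_ids) {
    rows <- which(ids == id)
    self_p <- m[rows, id]
    hit <- rows[which(self_p < self_alpha)]
    chosen <- if (length(hit) > 0) hit[1] else rows[1]
    keep[setdiff(rows, chosen)] <- FALSE
  }
  n_dup <- sum(!keep)
  if (n_unmatched + n_dup > 0)
    message(sprintf(
      "dropped %d unmatched and %d duplicate perturbations; %d retained",
      n_unmatched, n_dup, sum(keep)))
  structure(m[keep, , drop = FALSE],
            n_dropped_unmatched = n_unmatched,
            n_dropped_duplicates = n_dup)
}

new_effect_fractions <- function(outgoing, incoming, n_analyzed,
                                 threshold = NA_real_) {
  structure(list(outgoing = outgoing, incoming = incoming,
                 n_analyzed = n_analyzed, threshold = threshold),
            class = "grn_effect_fractions")
}

#' Per-gene effect fractions from a p-value table
#'
#' For each gene, the outgoing fraction is the share of the analyzed
#' network it affects when perturbed (p below `alpha`), and the incoming
#' fraction the share of perturbations that affect it; both are normalised
#' by the number of analyzed genes.
#'
#' @param table Matrix from [load_pairwise_pvalues()] (perturbations x
#'   genes).
#' @param alpha Significance threshold (default 0.05).
#' @return A `grn_effect_fractions` object with `outgoing`, `incoming` and
#'   `n_analyzed`.
#' @export
effect_fractions_from_pvalues <- function(table, alpha = 0.05) {
  m <- as.matrix(table)
  if (length(m) == 0) return(new_effect_fractions(numeric(0), numeric(0), 0L))
  sig <- m < alpha
  # exclude each perturbation's own target transcript where measured
  self <- intersect(rownames(m), colnames(m))
  for (id in self) sig[id, id] <- FALSE
  n_analyzed <- ncol(m)
  new_effect_fractions(outgoing = rowSums(sig) / n_analyzed,
                       incoming = colSums(sig) / n_analyzed,
                       n_analyzed = n_analyzed)
}

#' Per-gene effect fractions from a knockout screen
#'
#' Mirrors the construction used on experimental data but with a fixed
#' discovery rate: the significance threshold is set so that the top
#' `significance_rate` share of absolute effects over ordered expressed-gene
#' pairs is called significant. Ordered pairs tied exactly at the threshold
#' order statistic are not called.
#'
#' @param screen A `grn_screen`.
#' @param significance_rate Fraction of pairwise effects called significant
#'   (default 0.0316, i.e. 3.16%).
#' @return A `grn_effect_fractions` object with per-expressed-gene
#'   `outgoing` and `incoming` fractions, `n_analyzed` and the effect
#'   `threshold` used.
#' @export
effect_fractions_from_screen <- function(screen, significance_rate = 0.0316) {
  stopifnot(inherits(screen, "grn_screen"))
  stopifnot_scalar(significance_rate, "significance_rate", lower = 0, upper = 1)
  m <- screen_effect_matrix(screen)
  vals <- m[!is.na(m)]
  M <- length(vals)
  if (M == 0) return(new_effect_fractions(numeric(0), numeric(0), 0L))
  n_sig <- ceiling(significance_rate * M)
  thr <- if (n_sig >= M) -Inf else sort(vals, partial = M - n_sig)[M - n_sig]
  sig <- m > thr
  n_analyzed <- nrow(m)
  new_effect_fractions(outgoing = rowSums(sig, na.rm = TRUE) / n_analyzed,
                       incoming = colSums(sig, na.rm = TRUE) / n_analyzed,
                       n_analyzed = n_analyzed, threshold = thr)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Thin wrapper around [stats::ks.test()] returning the maximum ECDF gap
#' and its p-value (asymptotic by default, matching large-sample usage; set
#' `exact = TRUE` for small samples).
#'
#' @param sample_a,sample_b Numeric samples (non-empty).
#' @param exact Passed to [stats::ks.test()] (default `FALSE`).
#' @return List with `statistic` and `p_value`.
#' @export
ks_compare <- function(sample_a, sample_b, exact = FALSE) {
  if (length(sample_a) == 0 || length(sample_b) == 0)
    stop("both samples must be non-empty", call. = FALSE)
  kt <- suppressWarnings(stats::ks.test(sample_a, sample_b, exact = exact))
  list(statistic = unname(kt$statistic), p_value = unname(kt$p.value))
}

#' Rank simulated networks by similarity to a reference distribution
#'
#' Networks are ranked separately by descending KS p-value against the
#' reference outgoing and incoming effect-fraction distributions; the
#' selected set consists of the networks within rank `r` on *both* lists,
#' with `r` the smallest rank at which at least `k_select` networks qualify.
#' Ties are broken by network index.
#'
#' @param p_outgoing,p_incoming Per-network KS p-values against the
#'   reference outgoing / incoming distributions.
#' @param k_select Number of networks to select.
#' @return A list of class `grn_match_report`: `rank_outgoing`,
#'   `rank_incoming`, the joint rank `r`, and `selected` (indices).
#' @export
rank_best_matches <- function(p_outgoing, p_incoming, k_select = 1L) {
  stopifnot(length(p_outgoing) == length(p_incoming), length(p_outgoing) >= 1)
  stopifnot_scalar(k_select, "k_select", lower = 1,
                   upper = length(p_outgoing), integer = TRUE)
  r_out <- rank(-p_outgoing, ties.method = "first")
  r_in <- rank(-p_incoming, ties.method = "first")
  for (r in seq_along(p_outgoing)) {
    sel <- which(r_out <= r & r_in <= r)
    if (length(sel) >= k_select) {
      return(structure(list(rank_outgoing = r_out, rank_incoming = r_in,
                            r = r, selected = sel),
                       class = "grn_match_report"))
    }
  }
}

#' Compare simulated effect fractions to a reference
#'
#' Runs the KS comparison of each simulated network's outgoing and incoming
#' effect-fraction distributions against a reference (typically derived from
#' experimental data) and selects the best-matching networks.
#'
#' @param sim_fractions List of `grn_effect_fractions`, one per network.
#' @param reference A `grn_effect_fractions` for the reference data.
#' @param k_select Number of networks to select.
#' @param exact Passed to [ks_compare()].
#' @return A `grn_match_report` augmented with per-network KS statistics and
#'   p-values (`ks_outgoing`, `ks_incoming`, `p_outgoing`, `p_incoming`).
#' @export
match_report <- function(sim_fractions, reference, k_select = 1L,
                         exact = FALSE) {
  stopifnot(length(sim_fractions) >= 1,
            inherits(reference, "grn_effect_fractions"))
  ks_out <- lapply(sim_fractions, function(f)
    ks_compare(f$outgoing, reference$outgoing, exact = exact))
  ks_in <- lapply(sim_fractions, function(f)
    ks_compare(f$incoming, reference$incoming, exact = exact))
  rep <- rank_best_matches(vapply(ks_out, `[[`, numeric(1), "p_value"),
                           vapply(ks_in, `[[`, numeric(1), "p_value"),
                           k_select)
  rep$ks_outgoing <- vapply(ks_out, `[[`, numeric(1), "statistic")
  rep$ks_incoming <- vapply(ks_in, `[[`, numeric(1), "statistic")
  rep$p_outgoing <- vapply(ks_out, `[[`, numeric(1), "p_value")
  rep$p_incoming <- vapply(ks_in, `[[`, numeric(1), "p_value")
  rep
}
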