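# Plain-text readers/writers for the core objects. Edge lists and groups go
# to TSV with 0-based node IDs for interoperability; expression parameters
# are a JSON archive (per-gene vectors + sparse beta triplets + scalars).

#' Write / read a network as TSV
#'
#' `write_network()` writes `<stem>.edges.tsv` (`source<TAB>target`,
#' 0-based IDs) and `<stem>.groups.tsv` (`node<TAB>group`, 0-based labels).
#' `read_network()` reads them back.
#'
#' @param graph A `grn_graph`.
#' @param stem Output path stem (directories must exist).
#' @return `write_network()` returns the two file paths invisibly;
#'   `read_network()` returns a `grn_graph`.
#' @export
write_network <- function(graph, stem) {
  stopifnot(inherits(graph, "grn_graph"))
  ef <- paste0(stem, ".edges.tsv")
  gf <- paste0(stem, ".groups.tsv")
  write.table(data.frame(source = graph$edges[, 1] - 1L,
                         target = graph$edges[, 2] - 1L),
              ef, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(node = seq_len(graph$n_nodes) - 1L,
                         group = graph$group - 1L),
              gf, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(edges = ef, groups = gf))
}

#' @rdname write_network
#' @export
read_network <- function(stem) {
  ed <- read.delim(paste0(stem, ".edges.tsv"))
  gr <- read.delim(paste0(stem, ".groups.tsv"))
  as_grn_graph(n = nrow(gr),
               edges = cbind(ed$source + 1L, ed$target + 1L),
               group = gr$group + 1L)
}

#' Write / read expression parameters as JSON
#'
#' @param params A `grn_expression_params` object.
#' @param path Output `.json` path.
#' @return `read_expression_params()` returns a `grn_expression_params`.
#' @export
write_expression_params <- function(params, path) {
  stopifnot(inherits(params, "grn_expression_params"))
  trip <- Matrix::summary(params$beta)
  jsonlite::write_json(
    list(n = params$n, alpha = params$alpha, ell = params$ell,
         s = params$s, dt = params$dt,
         beta = list(i = trip$i, j = trip$j, x = trip$x)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_expression_params
#' @export
read_expression_params <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  beta <- Matrix::sparseMatrix(i = o$beta$i %||% integer(0),
                               j = o$beta$j %||% integer(0),
                               x = o$beta$x %||% numeric(0),
                               dims = c(o$n, o$n))
  expression_params(alpha = o$alpha, ell = o$ell, beta = beta,
                    s = o$s, dt = o$dt)
}

#' Write a steady state as TSV
#'
#' Columns: 0-based gene index, running-mean expression, expressed flag.
#'
#' @param state A `grn_steady_state`.
#' @param path Output path.
#' @export
write_steady_state <- function(state, path) {
  stopifnot(inherits(state, "grn_steady_state"))
  write.table(data.frame(gene = seq_along(state$xbar) - 1L,
                         xbar = state$xbar,
                         expressed = as.integer(state$expressed)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a log2 fold-change matrix as TSV
#'
#' Dense TSV with 0-based gene-index headers; rows are knockouts.
#'
#' @param screen A `grn_screen` or a plain matrix.
#' @param path Output path.
#' @export
write_log2fc <- function(screen, path) {
  m <- if (inherits(screen, "grn_screen")) screen$log2fc else as.matrix(screen)
  colnames(m) <- paste0("g", seq_len(ncol(m)) - 1L)
  write.table(m, path, sep = "\t", quote = FALSE,
              row.names = paste0("g", seq_len(nrow(m)) - 1L))
  invisible(path)
}

# Flat "key = value" experiment-config parser; '#' starts a comment.
read_experiment_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  keep <- grepl("=", lines, fixed = TRUE)
  out <- list()
  for (i in which(keep)) {
    kv <- strsplit(lines[i], "=", fixed = TRUE)[[1]]
    if (length(kv) != 2)
      stop(sprintf("config line %d: expected 'key = value'", i), call. = FALSE)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  attr(out, "path") <- path
  out
}
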