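# Internal helpers.

# Evaluate `expr` under a temporary R RNG state seeded with `seed`,
# restoring the caller's state afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

stopifnot_scalar <- function(x, name, lower = -Inf, upper = Inf,
                             integer = FALSE, strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (integer && x != round(x))
    stop(sprintf("`%s` must be an integer", name), call. = FALSE)
  if (strict_lower) {
    if (x <= lower) stop(sprintf("`%s` must be > %s", name, lower), call. = FALSE)
  } else if (x < lower) {
    stop(sprintf("`%s` must be >= %s", name, lower), call. = FALSE)
  }
  if (x > upper) stop(sprintf("`%s` must be <= %s", name, upper), call. = FALSE)
  invisible(x)
}

# C++ entry points take the seed as a non-negative double below 2^53.
sanitize_seed <- function(seed) {
  seed <- as.numeric(seed)
  if (!is.finite(seed)) stop("`seed` must be a finite number", call. = FALSE)
  abs(seed) %% 2^31
}

`%||%` <- function(a, b) if (is.null(a)) b else a
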