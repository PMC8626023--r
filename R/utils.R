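# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# global RNG stream is left untouched. `seed = NULL` uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

stop_if_not_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (x < min) {
    stop(sprintf("`%s` must be >= %g (got %g)", name, min, x), call. = FALSE)
  }
  invisible(x)
}

# Ordinal field check with the field name in the error, per the scoring
# contract (out-of-range input is rejected with the offending field named).
check_ordinal <- function(x, name, lo, hi) {
  if (any(!is.finite(x)) || any(x != round(x)) || any(x < lo) || any(x > hi)) {
    stop(sprintf("`%s` must be an integer in [%d, %d]", name, lo, hi),
         call. = FALSE)
  }
  invisible(as.integer(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
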