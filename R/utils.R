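#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded helpers never disturb the
#' caller's RNG stream. All randomness in the package flows through this.
#'
#' @param seed integer seed (kept below 2^31 by callers).
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-stage seed derivation; double arithmetic is exact here
# (< 2^53) and the result stays below 2^31.
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(stage) * 9176) %% 2147483000)
}

rms <- function(x) sqrt(mean(x^2))

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(ok, fmt, ...) if (!isTRUE(ok)) stopf(fmt, ...)
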