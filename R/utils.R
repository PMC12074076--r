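#' @keywords internal
"_PACKAGE"

## Named-stream seed splitting: one user-facing integer seed drives every
## stochastic stage, but each stage (cohort, geometry, noise, ...) gets its
## own derived sub-seed so stages are independently reproducible.
stream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  ## keep the derived seed a valid 32-bit integer
  as.integer((abs(seed) * 7919 + h * 104729) %% .Machine$integer.max)
}

## Run `expr` under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_arg <- function(...) stop(..., call. = FALSE)

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != round(x)) {
    stop_arg(sprintf("`%s` must be an integer >= %d", name, min))
  }
  as.integer(x)
}
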