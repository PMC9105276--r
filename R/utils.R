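## internal helpers: argument validation and seed plumbing

assert_proportion <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single proportion in [0, 1], got %s.",
                  name, deparse(x)),
          class = "dormantx_config_error")
  }
  invisible(x)
}

assert_positive <- function(x, name, integer = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) && x > 0
  if (ok && integer) ok <- x == as.integer(x)
  if (!ok) {
    abort(sprintf("`%s` must be a single positive %s, got %s.",
                  name, if (integer) "integer" else "number", deparse(x)),
          class = "dormantx_config_error")
  }
  invisible(x)
}

## Run `expr` under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Deterministic per-stage seed derived from a master seed; keeps results
## reproducible from one flag while decoupling stages' RNG streams.
## Kept below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(master, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131L)
  as.integer((as.double(master) * 7919 + h) %% 2147483629)
}

`%||%` <- rlang::`%||%`
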