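# Internal helpers shared across modules.

# Evaluate expr with a locally seeded RNG, restoring global RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Derive a child seed from a parent seed and a stream index, staying within
# 32-bit integer range.
childSeed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(stream)) %% 2147483647)
}

stopIf <- function(cond, ...) if (cond) stop(sprintf(...), call. = FALSE)

logMsg <- function(...) message(sprintf(...))
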