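# Internal helpers shared across modules.

# Evaluate `expr` under a reproducible RNG state without disturbing the
# caller's stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream-specific child seed from a master seed; stays within
# 32-bit integer range.
derive_seed <- function(seed, stream) {
  as.integer(((as.numeric(seed) %% 2147483647) * 48271 +
                7919 * stream) %% 2147483647)
}

stop_if_not_scalar_pos <- function(x, name, allow_zero = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (x > 0 || (allow_zero && x >= 0))
  if (!ok) stop(sprintf("`%s` must be a single %s number", name,
                        if (allow_zero) "non-negative" else "positive"),
                call. = FALSE)
  invisible(x)
}
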