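# Internal helpers: deterministic seed derivation and scoped RNG use.

# Mix an arbitrary tuple of non-negative integers into one 32-bit seed.
# Multiplicative-congruential mixing in double precision; all intermediates
# stay below 2^53 so the arithmetic is exact, and the result is < 2^31.
mix_seed <- function(...) {
  v <- as.numeric(c(...))
  stopifnot(all(is.finite(v)))
  s <- 104729
  for (x in v) s <- (s * 69069 + abs(x) + 1) %% 2147483629
  as.integer(s)
}

# Evaluate `code` under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}
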