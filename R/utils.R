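# Internal helpers.

# Evaluate expr with a locally-set RNG seed, restoring the caller's RNG
# state afterwards. seed = NULL leaves the RNG untouched.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Clamp correlations away from +/-1 before atanh.
clampR <- function(r, eps = 1e-7) {
  pmin(pmax(r, -1 + eps), 1 - eps)
}

stopIfNot <- function(cond, msg, ...) {
  if (!cond) stop(sprintf(msg, ...), call. = FALSE)
}
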