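# Seeding helpers: every stochastic routine takes an explicit seed and
# restores the caller's RNG state, so package functions never perturb the
# user's random stream.

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the given seed, evaluates `expr`, then restores the caller's
#' `.Random.seed` (or removes it if none existed).
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a child seed from a master seed and an index
#'
#' Stable affine hash modulo a 31-bit prime, so derived seeds stay valid R
#' integers and adding streams never shifts existing ones.
#'
#' @param seed master seed.
#' @param index stream index (integer or string; strings are hashed).
#' @return integer in [1, 2^31 - 2].
#' @export
derive_seed <- function(seed, index) {
  m <- 2147483647
  idx <- if (is.character(index)) stable_hash(index) else as.numeric(index)
  as.integer(((as.numeric(seed) %% m) * 48271 + idx * 7919) %% (m - 1) + 1)
}

# deterministic 31-bit string hash (polynomial rolling hash)
stable_hash <- function(s) {
  m <- 2147483647
  h <- 0
  for (c in utf8ToInt(s)) h <- (h * 131 + c) %% m
  h
}
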