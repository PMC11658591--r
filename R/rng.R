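#' Derive a reproducible sub-seed
#'
#' Mixes a master seed with one or more integer stream identifiers into a
#' 31-bit seed, so each cohort / trajectory / generator draws from its own
#' reproducible stream. Simple multiplicative hash; collisions are harmless
#' (streams only need to be decorrelated, not cryptographic).
#'
#' @param master Integer master seed.
#' @param ... Integer stream identifiers (cohort id, day index, ...).
#' @return Integer in [1, 2^31 - 2].
#' @export
derive_seed <- function(master, ...) {
  ids <- c(as.numeric(master), vapply(list(...), as.numeric, 0))
  h <- 0
  m <- 2147483647  # 2^31 - 1, prime
  for (x in ids) h <- (h * 48271 + (x %% m) + 11) %% m
  as.integer(h %% (m - 1) + 1)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, runs `expr`, and restores the caller's RNG state, so
#' seeded generators are pure functions that do not disturb the global
#' random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
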