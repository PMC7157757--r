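#' Evaluate an expression with a temporary RNG seed
#'
#' Seeds the generator, evaluates `expr`, and restores the caller's RNG
#' state, so seeded package functions never disturb the session's stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a per-purpose sub-seed from a global seed
#'
#' Lets one user-facing seed drive several independent generators: each
#' purpose string hashes to its own 31-bit sub-seed, deterministically.
#'
#' @param seed integer global seed.
#' @param purpose short string naming the stream (e.g. `"cds"`).
#' @return Integer sub-seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, purpose) {
  h <- sum(utf8ToInt(purpose) * seq_along(utf8ToInt(purpose)))
  as.integer((as.double(seed) * 48271 + h * 16807) %% (2^31 - 1))
}
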