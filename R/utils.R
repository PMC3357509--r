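#' Run code with a temporary RNG seed
#'
#' Seeds the R random number generator, evaluates `expr`, and restores the
#' caller's generator state, so seeded components never perturb each other.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Derive a named sub-seed from a global seed
#'
#' One global seed fans out into independent, reproducible streams for the
#' package's seeded components (population initialisation, splits,
#' replicate runs). The derivation hashes the stream name onto a 31-bit
#' integer so any derived seed is a valid R seed.
#'
#' @param seed integer global seed.
#' @param name character stream name, e.g. `"population3"` or `"split"`.
#' @return a positive integer seed below `2^31`.
#' @export
derive_seed <- function(seed, name) {
  h <- 0
  for (code in utf8ToInt(name)) h <- (h * 131 + code) %% 2147483647
  as.integer((h + as.numeric(seed) * 2654435761) %% 2147483647) + 1L
}
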