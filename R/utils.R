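# Internal helpers: seeded evaluation and named RNG substreams.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded package internals
#' never perturb user-level random number streams.
#'
#' @param seed integer seed, or `NULL` to leave the RNG alone.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a named RNG substream seed from a master seed
#'
#' All stochastic stages of the package draw their seeds from one master
#' seed through this function, so that a study is reproducible as a whole
#' while stages remain independently re-runnable.
#'
#' @param master integer master seed.
#' @param stream character stage name (e.g. `"proteome"`, `"tree"`).
#' @return An integer in `[1, 2^31 - 2]`.
#' @export
substream_seed <- function(master, stream) {
  stopifnot(length(master) == 1, is.finite(master), is.character(stream))
  h <- 0
  for (k in utf8ToInt(stream)) h <- (h * 131 + k) %% 2147483647
  s <- (as.double(master) %% 2147483647) * 69621 + h
  as.integer(s %% 2147483646 + 1)
}
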