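# Named RNG substreams: every stochastic stage (background wiring, assembly
# membership, initial conditions, cue sampling, ...) draws from its own
# deterministic substream of the experiment seed, so stages can be
# regenerated independently of each other.

substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  ch <- utf8ToInt(stream)
  h <- sum(ch * seq_along(ch) * 131) %% 1000003
  as.integer((abs(seed) * 48271 + h * 2017) %% 2147483629)
}

#' Evaluate code under a named, seed-derived RNG substream
#'
#' The global RNG state is saved and restored, so substream draws never
#' perturb user-level randomness.
#'
#' @param seed integer experiment seed.
#' @param stream character substream label, e.g. `"background"`.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @export
with_substream <- function(seed, stream, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, stream))
  code
}
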