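# Private seeded RNG stream. Every stochastic operation in the package draws
# from one of these, so results are bit-reproducible for a given seed and the
# user's global RNG state is never touched.
local_rng <- function(seed) {
  state <- NULL
  draw <- function(f) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    if (is.null(state)) set.seed(seed)
    else assign(".Random.seed", state, envir = globalenv())
    on.exit({
      state <<- get(".Random.seed", envir = globalenv())
      if (is.null(old))
        rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    f()
  }
  list(
    int = function(n) draw(function() sample.int(n, 1L)),
    sample_int = function(n, k, prob = NULL)
      draw(function() sample.int(n, k, replace = FALSE, prob = prob)),
    runif = function(n, min = 0, max = 1)
      draw(function() stats::runif(n, min, max)),
    rnorm = function(n, mean = 0, sd = 1)
      draw(function() stats::rnorm(n, mean, sd))
  )
}

#' Derive a stage seed from a run seed
#'
#' Stage-level reproducibility without seed collisions: the run seed is
#' combined with a hash of the stage name, kept inside the 32-bit integer
#' range.
#'
#' @param seed integer run seed.
#' @param stage stage name (character).
#' @return integer seed for the stage.
#' @export
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}
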