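# Internal helpers.

# A self-contained seeded RNG stream. Draws advance the stream's own state
# and leave the caller's .Random.seed untouched, so every generator in the
# package is reproducible from its `seed` argument without clobbering the
# session RNG.
local_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  genv <- globalenv()
  old <- get0(".Random.seed", envir = genv, inherits = FALSE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  env$state <- get(".Random.seed", envir = genv)
  if (is.null(old)) {
    rm(".Random.seed", envir = genv)
  } else {
    assign(".Random.seed", old, envir = genv)
  }
  with_state <- function(f) {
    force(f)
    function(...) {
      outer <- get0(".Random.seed", envir = genv, inherits = FALSE)
      assign(".Random.seed", env$state, envir = genv)
      on.exit({
        env$state <- get(".Random.seed", envir = genv)
        if (is.null(outer)) {
          if (exists(".Random.seed", envir = genv, inherits = FALSE))
            rm(".Random.seed", envir = genv)
        } else {
          assign(".Random.seed", outer, envir = genv)
        }
      })
      f(...)
    }
  }
  list(
    runif      = with_state(stats::runif),
    rnorm      = with_state(stats::rnorm),
    rbinom     = with_state(stats::rbinom),
    sample     = with_state(function(x, size = length(x), replace = FALSE)
                              sample(x, size, replace)),
    sample_int = with_state(function(n, size, replace = FALSE)
                              sample.int(n, size, replace))
  )
}

logit <- function(p) stats::qlogis(p)
inv_logit <- function(x) stats::plogis(x)
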