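# Seeded random-number streams that do not disturb the caller's RNG state.

#' Create an isolated seeded RNG stream
#'
#' Returns an object with `sample_int(n, k)`, `runif(n)`, `rnorm(n)` and
#' `shuffle(x)` methods drawing from a private Mersenne-Twister state seeded
#' with `seed`.  The global `.Random.seed` is left untouched.
#'
#' @param seed integer seed.
#' @return an environment with drawing functions.
#' @export
make_rng <- function(seed) {
  self <- new.env(parent = emptyenv())
  gl <- globalenv()
  saved_global <- function() {
    if (exists(".Random.seed", envir = gl, inherits = FALSE))
      get(".Random.seed", envir = gl) else NULL
  }
  old <- saved_global()
  set.seed(as.integer(seed))
  self$state <- get(".Random.seed", envir = gl)
  if (!is.null(old)) assign(".Random.seed", old, envir = gl)
  else rm(".Random.seed", envir = gl)

  with_state <- function(f) {
    old <- saved_global()
    assign(".Random.seed", self$state, envir = gl)
    on.exit({
      self$state <- get(".Random.seed", envir = gl)
      if (!is.null(old)) assign(".Random.seed", old, envir = gl)
      else if (exists(".Random.seed", envir = gl, inherits = FALSE))
        rm(".Random.seed", envir = gl)
    })
    f()
  }
  self$sample_int <- function(n, k = 1L, replace = FALSE)
    with_state(function() sample.int(n, k, replace = replace))
  self$runif <- function(n = 1L, min = 0, max = 1)
    with_state(function() stats::runif(n, min, max))
  self$rnorm <- function(n = 1L, mean = 0, sd = 1)
    with_state(function() stats::rnorm(n, mean, sd))
  self$shuffle <- function(x) with_state(function() x[sample.int(length(x))])
  # derive a child seed (kept below 2^31) for nested streams
  self$child_seed <- function()
    with_state(function() sample.int(2147483646L, 1L))
  self
}

`%||%` <- function(a, b) if (is.null(a)) b else a
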