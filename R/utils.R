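# Internal RNG plumbing. Every stochastic operation in the package draws from
# a local_rng stream so (a) identical seeds give identical results regardless
# of call order elsewhere, and (b) the caller's .Random.seed is never touched.

local_rng <- function(seed) {
  seed <- as.integer(seed)
  env <- new.env(parent = emptyenv())
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  set.seed(seed)
  env$state <- get(".Random.seed", envir = genv, inherits = FALSE)
  if (had) assign(".Random.seed", old, envir = genv) else
    rm(".Random.seed", envir = genv)

  with_state <- function(f) {
    force(f)
    function(...) {
      had_out <- exists(".Random.seed", envir = genv, inherits = FALSE)
      outer <- if (had_out) get(".Random.seed", envir = genv, inherits = FALSE)
      assign(".Random.seed", env$state, envir = genv)
      on.exit({
        env$state <- get(".Random.seed", envir = genv, inherits = FALSE)
        if (had_out) assign(".Random.seed", outer, envir = genv) else
          rm(".Random.seed", envir = genv)
      })
      f(...)
    }
  }

  list(
    runif = with_state(stats::runif),
    rnorm = with_state(stats::rnorm),
    rgamma = with_state(stats::rgamma),
    rbinom = with_state(stats::rbinom),
    sample_int = with_state(function(n, size = n, replace = FALSE)
      sample.int(n, size = size, replace = replace)),
    # length-safe vector sampling (never the 1:x surprise)
    sample = with_state(function(x, size = length(x), replace = FALSE)
      x[sample.int(length(x), size = size, replace = replace)]),
    # derive a child seed for a sub-stream
    child_seed = with_state(function()
      sample.int(.Machine$integer.max, 1L))
  )
}

# Deterministic seed derivation: global seed + stage name -> per-stage seed,
# so any pipeline stage can be re-run in isolation with the same stream.
derive_seed <- function(seed, stage) {
  codes <- utf8ToInt(as.character(stage))
  h <- 0
  for (cc in codes) h <- (h * 31 + cc) %% 2147483647
  as.integer((as.numeric(seed) * 2654435761 + h) %% 2147483647) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

genome_key <- function(genome) {
  if (is.list(genome)) genome <- unlist(genome, use.names = FALSE)
  paste(format(genome, digits = 17, trim = TRUE), collapse = ",")
}
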