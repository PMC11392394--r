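#' @importFrom stats runif rnorm rnbinom rgamma rgeom plogis pgamma qgamma
#'   qnorm uniroot sd setNames approx
#' @importFrom utils read.csv write.csv packageVersion
NULL

# Reproducible RNG scaffolding.
#
# Monte Carlo runs use the L'Ecuyer-CMRG generator so that a single master
# seed can spawn independent streams (one per capacity level) and substreams
# (one per replicate) via parallel::nextRNGStream()/nextRNGSubStream().
# Replicates are therefore reproducible and order-independent.  All helpers
# save and restore the caller's RNG state, so package code never perturbs the
# user's session RNG.

# Evaluate `code` with the global RNG temporarily set to `state`:
# either an integer seed (Mersenne-Twister, as set.seed) or a saved
# .Random.seed vector.
with_rng <- function(state, code) {
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  old_kind <- RNGkind()
  on.exit({
    RNGkind(old_kind[1L], old_kind[2L], old_kind[3L])
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  }, add = TRUE)
  if (length(state) == 1L) {
    set.seed(state)
  } else {
    RNGkind("L'Ecuyer-CMRG")
    assign(".Random.seed", state, envir = globalenv())
  }
  code
}

# Root stream for a master seed (L'Ecuyer-CMRG .Random.seed vector).
rng_root_stream <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  with_rng(0L, {
    RNGkind("L'Ecuyer-CMRG")
    set.seed(as.integer(seed))
    get(".Random.seed", globalenv())
  })
}

# n successive independent streams descended from `stream`.
rng_streams <- function(stream, n) {
  out <- vector("list", n)
  s <- stream
  for (i in seq_len(n)) {
    s <- parallel::nextRNGStream(s)
    out[[i]] <- s
  }
  out
}

# n successive substreams of `stream` (used for replicates within a run).
rng_substreams <- function(stream, n) {
  out <- vector("list", n)
  s <- stream
  for (i in seq_len(n)) {
    s <- parallel::nextRNGSubStream(s)
    out[[i]] <- s
  }
  out
}
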