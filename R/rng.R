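# Independent, resumable random streams. Each stream owns a private
# Mersenne-Twister state that is swapped into R's global generator only for
# the duration of a draw, so stimulus-policy randomness never perturbs
# virtual-subject randomness, and replications cannot leak state into each
# other or into the caller's session.

#' Seeded independent random stream
#'
#' @param seed Integer seed for this stream.
#' @return A list of draw functions sharing one private generator state:
#'   `runif(n)` (uniforms) and `sample_int(k)` (one uniform integer in
#'   `1..k`).
#' @export
rng_stream <- function(seed) {
  state <- NULL
  with_state <- function(f) {
    old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (is.null(state)) set.seed(seed)
    else assign(".Random.seed", state, envir = globalenv())
    on.exit({
      state <<- get(".Random.seed", envir = globalenv(), inherits = FALSE)
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    f()
  }
  list(
    seed = seed,
    runif = function(n = 1) with_state(function() stats::runif(n)),
    sample_int = function(k) with_state(function() sample.int(k, 1))
  )
}

# Deterministic per-replication seed pairs (policy stream, subject stream)
# derived from one base seed; pairwise distinct by sampling without
# replacement.
.replication_seeds <- function(base_seed, replications) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(base_seed)
  s <- sample.int(.Machine$integer.max - 1L, 2L * replications)
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, envir = globalenv())
  matrix(s, ncol = 2, dimnames = list(NULL, c("policy", "subject")))
}
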