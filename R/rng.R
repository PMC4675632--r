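#' Independent seeded random streams
#'
#' A run of the simulator draws from two independent uniform random streams,
#' one for the environment (cue scheduling, delay sampling, shock delivery)
#' and one for the agent (softmax plan sampling, controller sampling). Each
#' stream is a self-contained generator state seeded deterministically from
#' the run's master seed, so that two agents sharing a master seed are yoked
#' to the same environment draws even when their actions differ.
#'
#' @param seed integer seed for the stream.
#' @return An object of class `rng_stream`.
#' @examples
#' s <- rng_stream(42)
#' stream_runif(s, 3)
#' @export
rng_stream <- function(seed) {
  s <- new.env(parent = emptyenv())
  old <- .save_global_seed()
  set.seed(as.integer(seed))
  s$state <- get(".Random.seed", envir = globalenv())
  .restore_global_seed(old)
  class(s) <- "rng_stream"
  s
}

.save_global_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.restore_global_seed <- function(old) {
  if (!is.null(old)) {
    assign(".Random.seed", old, envir = globalenv())
  } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    rm(".Random.seed", envir = globalenv())
  }
  invisible(NULL)
}

#' Draw uniforms from a stream
#'
#' Advances the stream's private generator state; the session's global
#' generator is left untouched.
#'
#' @param stream an [rng_stream()].
#' @param n number of draws.
#' @return numeric vector of `n` draws in (0, 1).
#' @export
stream_runif <- function(stream, n = 1L) {
  stopifnot(inherits(stream, "rng_stream"))
  old <- .save_global_seed()
  assign(".Random.seed", stream$state, envir = globalenv())
  x <- stats::runif(n)
  stream$state <- get(".Random.seed", envir = globalenv())
  .restore_global_seed(old)
  x
}

#' Derive a substream seed from a master seed
#'
#' Deterministic integer mixing of a master seed with any number of integer
#' keys (stream role, block index, replicate number, ...). Always returns a
#' value in `[1, 2^31 - 2]` so it is a valid input to [set.seed()].
#'
#' @param seed master seed (integer).
#' @param ... integer keys identifying the substream.
#' @return integer seed.
#' @export
derive_seed <- function(seed, ...) {
  keys <- c(as.numeric(seed), vapply(list(...), as.numeric, numeric(1)))
  m <- 2147483647 # 2^31 - 1, prime
  s <- 0
  for (k in keys) {
    # multiplicative congruential mixing; doubles are exact below 2^53
    s <- ((s + k + 1) * 48271) %% m
    s <- (s * 69621 + 1) %% m
  }
  as.integer(s %% (m - 1) + 1)
}
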