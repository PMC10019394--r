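#' Named reproducible random-number streams
#'
#' The simulator draws from several statistically independent processes
#' (founder influx, migration, somatic hypermutation, selection). Each gets
#' its own stream derived deterministically from one master seed, so toggling
#' one model feature does not perturb the draws of another.
#'
#' A stream is a small environment holding a private copy of R's Mersenne
#' Twister state; [withStream()] temporarily installs that state, evaluates an
#' expression, and saves the advanced state back.
#'
#' @param seed integer master seed (kept below 2^31).
#' @return `newRngStream()` returns a stream object (environment);
#'   `rngStreams()` returns a named list of streams.
#' @examples
#' s <- newRngStream(1L)
#' a <- withStream(s, runif(3))
#' b <- withStream(newRngStream(1L), runif(3))
#' stopifnot(identical(a, b))
#' @export
newRngStream <- function(seed) {
  seed <- as.integer(seed)
  stopifnot(is.finite(seed))
  e <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(seed)
  e$state <- get(".Random.seed", envir = globalenv())
  e$seed <- seed
  if (!is.null(old)) {
    assign(".Random.seed", old, envir = globalenv())
  } else {
    rm(".Random.seed", envir = globalenv())
  }
  class(e) <- "RngStream"
  e
}

#' @rdname newRngStream
#' @param stream a stream created by [newRngStream()].
#' @param expr expression evaluated with the stream's RNG state installed.
#' @export
withStream <- function(stream, expr) {
  stopifnot(inherits(stream, "RngStream"))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  assign(".Random.seed", stream$state, envir = globalenv())
  on.exit({
    stream$state <- get(".Random.seed", envir = globalenv())
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    }
  })
  expr
}

#' @rdname newRngStream
#' @param names character vector of stream names.
#' @export
rngStreams <- function(seed, names = c("influx", "migration", "shm",
                                       "selection", "germline")) {
  seed <- as.integer(seed)
  # distinct, deterministic sub-seeds; kept within 32-bit integer range
  sub <- (as.numeric(seed) * 48271 + 1000003 * seq_along(names)) %%
    2147483647
  streams <- lapply(as.integer(sub), newRngStream)
  names(streams) <- names
  streams
}
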