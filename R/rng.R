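#' Named random-number substreams
#'
#' A simulation holds independent named RNG streams (ignition, fire
#' placement, fire impacts, demography, litter disturbance) derived from one
#' master seed, so that toggling the fire module on or off does not perturb
#' the demographic draw sequence. Each stream is a saved `.Random.seed`
#' state; [with_stream()] swaps a stream in, evaluates an expression, and
#' saves the advanced state back.
#'
#' @param master_seed integer master seed.
#' @param names character vector of stream names.
#' @return an environment of class `fl_rng` holding one saved RNG state per
#'   stream name.
#' @examples
#' s <- rng_streams(1)
#' a <- with_stream(s, "demography", runif(3))
#' b <- with_stream(s, "ignition", runif(3))
#' @export
rng_streams <- function(master_seed,
                        names = c("ignition", "placement", "fire",
                                  "demography", "disturbance")) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L)
  env <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(as.integer(master_seed))
  seeds <- sample.int(.Machine$integer.max - 1L, length(names))
  for (i in seq_along(names)) {
    set.seed(seeds[[i]])
    assign(names[[i]], get(".Random.seed", envir = globalenv()), envir = env)
  }
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  class(env) <- "fl_rng"
  env
}

#' @rdname rng_streams
#' @param streams an `fl_rng` object.
#' @param name stream name to draw from.
#' @param expr expression evaluated with the stream's RNG state active.
#' @return for `with_stream`, the value of `expr`.
#' @export
with_stream <- function(streams, name, expr) {
  if (!exists(name, envir = streams, inherits = FALSE))
    stop_fl("unknown RNG stream '%s'", name)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  assign(".Random.seed", get(name, envir = streams), envir = globalenv())
  on.exit({
    assign(name, get(".Random.seed", envir = globalenv()), envir = streams)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  expr
}
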