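# Internal helpers shared across modules.

# Evaluate expr under a fixed RNG seed without disturbing the caller's RNG
# stream. All exported stochastic operations route their randomness through
# this so that identical (inputs, seed) give identical output.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a per-stage seed from a master seed
#'
#' Pipeline stages draw their randomness from seeds derived deterministically
#' from the master seed and the stage name, so any stage can be re-run on its
#' own and still reproduce the full-pipeline output. The derivation is
#' \code{(seed * 48271 + index * 9973) mod (2^31 - 1)} where \code{index} is
#' the stage's position in the fixed stage list
#' (timeline, behavior, spikes, classify).
#'
#' @param seed master seed, a single integer.
#' @param stage stage name, one of \code{"timeline"}, \code{"behavior"},
#'   \code{"spikes"}, \code{"classify"}, or an integer offset.
#' @return a single integer seed in \code{[0, 2^31 - 2]}.
#' @export
#' @examples
#' deriveSeed(1, "timeline")
#' deriveSeed(1, "spikes")
deriveSeed <- function(seed, stage) {
  stages <- c(timeline = 1, behavior = 2, spikes = 3, classify = 4)
  idx <- if (is.character(stage)) {
    if (!stage %in% names(stages)) stop("unknown stage: ", stage)
    stages[[stage]]
  } else as.numeric(stage)
  m <- 2147483647  # 2^31 - 1; double arithmetic is exact well past these products
  as.integer(((as.numeric(seed) %% m) * 48271 + idx * 9973) %% m)
}

# Strict half-open membership: is x in any [start, end)?
inAnyInterval <- function(x, start, end) {
  if (!length(start)) return(rep(FALSE, length(x)))
  i <- findInterval(x, start)
  i > 0L & x < end[pmax(i, 1L)]
}

stopIfNot <- function(cond, ...) if (!cond) stop(..., call. = FALSE)
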