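#' Derive a named RNG substream seed from a master seed
#'
#' Fans a single master seed out into independent, reproducible substreams so
#' that toggling one source of randomness (for example counting noise) does
#' not shift the draws of another (for example line jitter). The mapping is a
#' small deterministic hash of the stream name folded into the master seed,
#' kept within the 32-bit integer range.
#'
#' @param seed Master integer seed.
#' @param stream Character stream name, e.g. `"jitter"`, `"noise"`,
#'   `"phantom"`, `"folds"`.
#' @return An integer seed.
#' @export
#' @examples
#' substream_seed(1L, "jitter")
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 31 + ch) %% 1000003
  as.integer((abs(as.numeric(seed)) + h * 2654435) %% .Machine$integer.max)
}

# evaluate expr under a local RNG state seeded with `seed`; restores the
# caller's RNG afterwards so simulators do not disturb the global stream
with_substream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, stream))
  expr
}

assert_scalar_num <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
  if (positive && x <= 0) abort(sprintf("`%s` must be > 0", name))
  if (nonneg && x < 0) abort(sprintf("`%s` must be >= 0", name))
  invisible(x)
}
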