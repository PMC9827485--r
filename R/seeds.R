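# Deterministic seeding utilities.
#
# Every stochastic operation in the package takes an explicit integer seed.
# A master seed is expanded into independent substreams (one per slide, per
# annotator, per stage) so that any single artifact can be regenerated
# without replaying the whole study.

# evaluate `code` under `seed`, restoring the caller's RNG state afterwards
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("seed must be a single finite integer")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a substream seed from a master seed
#'
#' Hashes the master seed together with a stream label (e.g. slide id,
#' annotator id, stage name) into a new seed in `[1, 2^31 - 2]`. The mapping
#' is a plain polynomial string hash: deterministic across platforms and
#' sessions, and distinct labels give effectively independent substreams.
#'
#' @param seed master integer seed.
#' @param ... label components (coerced to character) identifying the stream.
#' @return A single integer seed.
#' @export
#' @examples
#' substream_seed(1, "slide", "s01_pb")
substream_seed <- function(seed, ...) {
  label <- paste(c(format(as.integer(seed)), as.character(unlist(list(...)))),
                 collapse = "/")
  m <- 2147483629  # largest prime below 2^31
  h <- as.integer(seed) %% m
  for (code in utf8ToInt(label)) {
    h <- (h * 131 + code) %% m
  }
  as.integer(h + 1L)
}
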