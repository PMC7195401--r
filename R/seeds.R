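#' Deterministic seed derivation
#'
#' Mixes a master seed with any number of integer or character tags into a
#' new seed in `[1, 2^31 - 2]`. Used to fan a single master seed out to
#' pipeline stages and to tie Monte-Carlo draws to slide/patch identity
#' (grid coordinates) rather than iteration order, so results are invariant
#' to patch ordering.
#'
#' The mix is a multiplicative-congruential hash carried out in double
#' precision: all intermediate products stay below 2^53 so the arithmetic
#' is exact.
#'
#' @param seed integer master seed.
#' @param ... integer or character tags to fold in.
#' @return a single integer seed, always in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' mix_seed(1, "train")
#' mix_seed(42, "mc", 3L, 5L, 2L)
mix_seed <- function(seed, ...) {
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (tag in list(...)) {
    vals <- if (is.character(tag)) {
      unlist(lapply(tag, utf8ToInt), use.names = FALSE)
    } else {
      as.numeric(tag)
    }
    for (v in vals) {
      h <- (h * 48271 + (v %% m) + 11) %% m
    }
  }
  as.integer(h %% (m - 2)) + 1L
}

# Run code under a fixed seed, restoring the caller's RNG state afterwards,
# so every generator is a pure function of its arguments.
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
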