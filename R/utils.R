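#' Derive a child RNG seed from a master seed
#'
#' Deterministically spawns sub-stream seeds so that each network draw, trial
#' set, shuffle set and train/test split has its own reproducible stream. Uses
#' a few rounds of a Lehmer-style congruential mix; all arithmetic stays below
#' 2^53 so the result is exact, and the returned seed is a positive 32-bit
#' integer.
#'
#' @param seed master seed (integer).
#' @param ... integer stream labels, e.g. `derive_seed(seed, network = 3, 2)`.
#' @return a single integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  ks <- as.double(unlist(list(...), use.names = FALSE))
  s <- as.double(abs(as.integer(seed)) %% 2147483647)
  for (k in c(ks, 17)) {
    s <- (s * 48271 + k * 9973 + 1) %% 2147483647
  }
  as.integer(s + 1)
}

# evaluate `expr` under a temporary RNG state seeded with `seed`
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

`%||%` <- function(x, y) if (is.null(x)) y else x
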