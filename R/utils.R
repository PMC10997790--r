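# Small internal helpers shared across modules.

#' Derive a reproducible sub-seed from a root seed and a stream name
#'
#' All stochastic stages draw their RNG state from a named substream of one
#' root seed, so any single stage can be reproduced in isolation. The
#' derivation is a small string hash folded into the root seed, kept below
#' 2^31 so it is always a valid R integer seed.
#'
#' @param seed integer root seed.
#' @param stream character stream name.
#' @return An integer seed.
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- 0
  for (k in utf8ToInt(stream)) h <- (h * 131 + k) %% 1000000007
  as.integer(((abs(seed) %% 65011 + 1) * 32003 + h) %% 2147483647)
}

# Run expr with a local RNG state seeded from `seed`; restores the caller's
# RNG so library code never clobbers user seeds.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

# Inverse-CDF sampler for a normal truncated to [lo, hi]; p in (0,1).
qtruncnorm <- function(p, mean, sd, lo, hi) {
  plo <- pnorm((lo - mean) / sd)
  phi <- pnorm((hi - mean) / sd)
  qnorm(plo + p * (phi - plo)) * sd + mean
}

# Argmax over rows of a probability matrix with ties broken toward the
# lowest (worst) category -- the package-wide declared tie rule.
argmax_low <- function(prob) {
  stopifnot(is.matrix(prob))
  max.col(prob, ties.method = "first")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
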