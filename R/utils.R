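# Internal helpers: seeding, argument checks, small numerics.

#' Derive a child seed from a base seed and stream offsets
#'
#' Mixes a base seed with one or more integer offsets into a new seed in
#' `[1, 2^31 - 2]`. Used to spawn independent, reproducible RNG substreams
#' (per patch, per MC pass, per fold, per acquisition step) from one master
#' seed, so results do not depend on generation order.
#'
#' @param seed Integer base seed.
#' @param ... Integer offsets identifying the substream.
#' @return A single integer seed.
#' @keywords internal
derive_seed <- function(seed, ...) {
  m <- 2147483647 # 2^31 - 1, Mersenne prime modulus
  s <- as.numeric(seed) %% m
  for (k in c(...)) {
    s <- (s * 48271 + as.numeric(k) * 16807 + 1) %% m
  }
  as.integer(s %% (m - 2) + 1)
}

# Run `expr` under a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

stopifnot_scalar_int <- function(x, name, min = -Inf) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != round(x) || x < min) {
    stop(sprintf("`%s` must be a single integer >= %s", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}

# Clamp numeric values into [lo, hi].
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Shannon entropy (nats) of a probability vector; 0 * log 0 := 0.
# The `+ 0` normalises IEEE negative zero (from -sum over log(1)) to +0.
shannon_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p)) + 0
}

# Trapezoidal area under y(x) with x ascending.
trapezoid_area <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (head(y, -1L) + tail(y, -1L)) / 2)
}

#' @importFrom utils head tail
NULL
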