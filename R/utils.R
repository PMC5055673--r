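# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. A NULL seed leaves the RNG untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic named substream: every stochastic stage of a run draws its own
# seed from the root seed plus a stage name, so stages can be regenerated
# independently. Kept below 2^31 - 1 (R integers are 32-bit).
substream_seed <- function(seed, name) {
  v <- utf8ToInt(name)
  h <- sum(v * seq_along(v)) %% 65521
  as.integer(((as.numeric(seed) %% 1000003) * 2011 + h) %% 2147483647)
}

# Product of probabilities, switching to log space when tiny values could
# underflow; exact prod() otherwise.
prod_prob <- function(x) {
  if (!length(x)) return(1)
  if (min(x) < 1e-12) {
    if (any(x == 0)) return(0)
    return(exp(sum(log(x))))
  }
  prod(x)
}

# Spearman rho that returns exactly 1 when the two rankings coincide
# (avoids last-ulp noise from the covariance ratio on identical inputs).
spearman_rho <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  if (all(rx == ry)) return(1)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(NA_real_)
  stats::cor(rx, ry)
}

assert_fraction <- function(x, name, closed_upper = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0 &&
    (if (closed_upper) x <= 1 else x < 1)
  if (!ok) {
    stop("'", name, "' must be a single number in (0, 1",
         if (closed_upper) "]" else ")", call. = FALSE)
  }
  invisible(x)
}
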