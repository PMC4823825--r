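# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards. `seed = NULL` leaves the RNG untouched.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Symmetric Dirichlet draw (one vector of length k).
rdirichlet1 <- function(k, alpha = 1) {
  g <- stats::rgamma(k, shape = alpha, rate = 1)
  if (sum(g) <= 0) g <- rep(1, k)  # degenerate underflow guard
  g / sum(g)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Clamp probabilities away from 0/1 for log-likelihood work.
clamp_prob <- function(p, eps = 1e-9) pmin(pmax(p, eps), 1 - eps)

stop_scalar_count <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x != floor(x)))
    stop(sprintf("'%s' must contain nonnegative integer counts", name), call. = FALSE)
  invisible(x)
}
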