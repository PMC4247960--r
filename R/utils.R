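# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed without disturbing the caller's RNG state.
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
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Draw `n` child seeds (< 2^31) reproducibly from a parent seed.
child_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

# Numerically stable logistic 1 / (1 + exp(-f)).
sigmoid_stable <- function(f) {
  out <- numeric(length(f))
  pos <- f >= 0
  out[pos] <- 1 / (1 + exp(-f[pos]))
  ef <- exp(f[!pos])
  out[!pos] <- ef / (1 + ef)
  out
}

# log(1 + exp(f)) without overflow.
log1pexp <- function(f) {
  pmax(f, 0) + log1p(exp(-abs(f)))
}

assert_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s].",
                  name, format(lower), format(upper)))
  }
  invisible(x)
}

# Mirror (reflective) index into 1..n, for boundary padding.
mirror_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- (i - 1L) %% (2L * (n - 1L))
  ifelse(p < n, p + 1L, 2L * n - 1L - p)
}
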