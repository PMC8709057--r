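# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards. Keeps deterministic sub-draws from
# perturbing an enclosing random stream (important for the campaign modes,
# whose chunked code draws must be identical across modes).
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  code
}

# Mix a base seed with a counter into a valid 32-bit seed. Used wherever a
# family of deterministic sub-streams is derived from one user-facing seed.
mix_seed <- function(seed, k) {
  s <- (as.double(seed) %% 1e6) * 2038074743 + as.double(k) * 97561
  as.integer(s %% 2147483629) + 1L
}

stop_arg <- function(...) stop(sprintf(...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_arg("`%s` must be a single finite number", name)
  if (x < lower || x > upper)
    stop_arg("`%s` must be in [%s, %s]", name, format(lower), format(upper))
  if (integer && x != round(x)) stop_arg("`%s` must be an integer", name)
  invisible(x)
}

# Soft amplitude limiter: identity up to `knee * bound`, smooth tanh
# compression above, asymptote at `bound`. Keeps physiological amplitudes
# untouched while guaranteeing |output| < bound.
soft_clip <- function(x, bound, knee = 0.8) {
  k <- knee * bound
  m <- bound - k
  over <- abs(x) > k
  if (any(over)) {
    x[over] <- sign(x[over]) * (k + m * tanh((abs(x[over]) - k) / m))
  }
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
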