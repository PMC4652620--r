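# Internal helpers shared across modules.

# Geometric mean of strictly positive values.
geomean <- function(x) exp(mean(log(x)))

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Lowess smoother evaluated back at the original x positions.
# stats::lowess returns fits at sorted unique x; interpolate to recover
# a per-point correction (constant extrapolation beyond the data range).
lowess_fit <- function(x, y, span) {
  fit <- stats::lowess(x, y, f = span)
  stats::approx(fit$x, fit$y, xout = x, rule = 2, ties = mean)$y
}
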