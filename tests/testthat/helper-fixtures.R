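# Shared fixtures, built in code.

cm <- function(values, features = NULL, samples = NULL, is_spikein = NULL) {
  values <- as.matrix(values)
  if (is.null(features)) features <- sprintf("f%02d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(values)))
  dimnames(values) <- list(features, samples)
  count_matrix(values, is_spikein)
}

# Two proportional columns plus structure: column 2 = 2x column 1.
proportional_cm <- function() cm(cbind(c(10, 20, 30, 40), c(20, 40, 60, 80)))

# A deterministic pseudo-random integer matrix (no RNG state touched).
lcg_matrix <- function(nr, nc, max = 200, seed = 7) {
  v <- numeric(nr * nc)
  state <- seed
  for (i in seq_along(v)) {
    state <- (1103515245 * state + 12345) %% 2^31
    v[i] <- state %% (max + 1)
  }
  cm(matrix(v, nr, nc))
}

default_dataset <- function(seed = 1, ...) {
  simulate_dataset(sim_config(seed = seed, ...))
}
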