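# Independent brute-force TMM oracle: recomputes the weighted trimmed mean
# by explicit enumeration (loops + quantile thresholds), sharing no code with
# the package implementation.
brute_tmm_log_factor <- function(xk, xr, sk, sr, trim_M = 0.30, trim_A = 0.05) {
  keep <- which(xk > 0 & xr > 0)
  M <- A <- v <- numeric(0)
  for (i in keep) {
    pk <- xk[i] / sk
    pr <- xr[i] / sr
    M <- c(M, log2(pk / pr))
    A <- c(A, 0.5 * log2(pk * pr))
    v <- c(v, (sk - xk[i]) / (sk * xk[i]) + (sr - xr[i]) / (sr * xr[i]))
  }
  loM <- quantile(M, trim_M / 2); hiM <- quantile(M, 1 - trim_M / 2)
  loA <- quantile(A, trim_A / 2); hiA <- quantile(A, 1 - trim_A / 2)
  surv <- M >= loM & M <= hiM & A >= loA & A <= hiA
  num <- den <- 0
  for (i in which(surv)) {
    num <- num + M[i] / v[i]
    den <- den + 1 / v[i]
  }
  num / den
}
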