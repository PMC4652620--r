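test_that("cpm rescales every sample to one million and is depth-invariant", {
  m <- lcg_matrix(30, 3)
  res <- normalize_cpm(m)
  expect_equal(unname(colSums(res$normalized$counts)), rep(1e6, 3), tolerance = 1e-12)
  expect_equal(res$normalized$counts[5, 1],
               m$counts[5, 1] * 1e6 / sum(m$counts[, 1]))
  # proportional columns become identical
  p <- normalize_cpm(proportional_cm())$normalized
  expect_equal(p$counts[, 1], p$counts[, 2], ignore_attr = TRUE)
  # already at 1e6 -> unchanged
  one_m <- cm(matrix(c(4e5, 6e5, 2e5, 8e5), 2, 2))
  expect_equal(normalize_cpm(one_m)$normalized$counts, one_m$counts)
  expect_error(normalize_cpm(cm(matrix(c(1, 0), 1, 2))), "zero-sum")
})

test_that("total-count scaling uses the median-size baseline with factor 1", {
  vals <- rbind(c(20, 40, 80), c(80, 160, 320))  # sums 100, 200, 400
  m <- cm(vals)
  res <- normalize_total_count(m)
  expect_equal(unname(res$factors$factors), c(2, 1, 0.5))
  expect_equal(res$factors$reference, "s02")
  expect_equal(unname(colSums(res$normalized$counts)), rep(200, 3))
  expect_equal(res$normalized$counts[, 2], m$counts[, 2])
})

test_that("upper-quartile factors have geometric mean 1 and equalize proportional columns", {
  m <- cm(matrix(c(1, 5, 10, 40, 3, 15, 30, 120), 4, 2))  # B = 3 x A
  res <- normalize_upper_quartile(m)
  expect_equal(unname(res$factors$factors), c(sqrt(3), sqrt(3) / 3))
  expect_equal(res$normalized$counts[, 1], res$normalized$counts[, 2],
               ignore_attr = TRUE)
  # identical columns: factors 1, unchanged
  id <- cm(cbind(c(1, 5, 9), c(1, 5, 9)))
  rid <- normalize_upper_quartile(id)
  expect_equal(unname(rid$factors$factors), c(1, 1))
  expect_equal(rid$normalized$counts, id$counts)
  # an all-zero feature does not move the quartile
  withz <- cm(rbind(id$counts, c(0, 0)))
  expect_equal(unname(normalize_upper_quartile(withz)$factors$factors), c(1, 1))
})

test_that("TMM matches an independent brute-force oracle and handles degenerate cases", {
  # 20-feature toy: 4 features strongly up in B, 16 equal between samples.
  # Library sizes are powers of two (4096 and 8192) so the depth-scaled
  # ratios — and hence the tied M-values — are exactly representable and the
  # trim boundaries are unambiguous for both implementations.
  base <- c(seq(104, 344, by = 16), 50, 100, 150, 212)
  stopifnot(sum(base) == 4096)
  xB <- base
  xB[17:20] <- base[17:20] * 9
  stopifnot(sum(xB) == 8192)
  m <- cm(cbind(base, xB))
  res <- normalize_tmm(m, reference = "s01")
  expected_logf <- brute_tmm_log_factor(xB, base, sum(xB), sum(base))
  f <- 2^c(0, expected_logf)
  f <- f / exp(mean(log(f)))
  expect_equal(unname(res$factors$factors), unname(f), tolerance = 1e-12)
  # identical to reference -> factor 1
  mm <- cm(cbind(base, base))
  expect_equal(unname(normalize_tmm(mm, reference = "s01")$factors$factors), c(1, 1))
  # pure depth change: column times c gives all M = 0 -> factor 1
  md <- cm(cbind(base, base * 4))
  expect_equal(unname(normalize_tmm(md, reference = "s01")$factors$factors), c(1, 1))
})

test_that("TMM factors have geometric mean 1 and resist a pure depth change", {
  m <- filter_low_counts(default_dataset(seed = 21)$counts)
  res <- normalize_tmm(m)
  expect_equal(exp(mean(log(res$factors$factors))), 1, tolerance = 1e-9)
  # multiplying one column by c leaves its factor (nearly) unchanged:
  # M and A are depth-scaled, so survivors and M are identical and only the
  # delta-method weights shift
  scaled <- m
  scaled$counts[, 3] <- scaled$counts[, 3] * 5
  scaled <- count_matrix(scaled$counts, scaled$is_spikein)
  ref <- samples(m)[1]
  f1 <- normalize_tmm(m, reference = ref)$factors$factors
  f2 <- normalize_tmm(scaled, reference = ref)$factors$factors
  expect_equal(unname(f2[3] / f1[3]), 1, tolerance = 0.02)
})

test_that("median-of-ratios size factors match hand computation and DESeq2, and scale equivariantly", {
  m <- cm(rbind(c(100, 200), c(50, 100), c(10, 20)))
  res <- normalize_median_ratio(m)
  expect_equal(unname(res$factors$size_factors), c(1 / sqrt(2), sqrt(2)))
  # identical columns -> size factors 1
  id <- cm(cbind(c(3, 8), c(3, 8)))
  expect_equal(unname(normalize_median_ratio(id)$factors$size_factors), c(1, 1))
  # scaling equivariance: multiplying one column by 10 multiplies the RATIO
  # of its size factor to any other by exactly 10 (the per-feature geometric
  # means absorb a factor 10^(1/n), so individual factors move by 10^((n-1)/n))
  m10 <- cm(rbind(c(1000, 200), c(500, 100), c(100, 20)))
  sf0 <- normalize_median_ratio(m)$factors$size_factors
  sf10 <- normalize_median_ratio(m10)$factors$size_factors
  expect_equal(unname(sf10[1] / sf10[2]), unname(10 * sf0[1] / sf0[2]))
  expect_equal(unname(sf10), unname(sf0 * c(10, 1) * 10^(-1 / 2)))
  # independent cross-check on a larger matrix
  skip_if_not_installed("DESeq2")
  big <- filter_low_counts(default_dataset(seed = 5)$counts)
  ours <- normalize_median_ratio(big)$factors$size_factors
  theirs <- DESeq2::estimateSizeFactorsForMatrix(big$counts)
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-10)
  expect_error(normalize_median_ratio(cm(rbind(c(0, 1), c(2, 0)))), "filter")
})

test_that("MA statistics follow the log-ratio / average-intensity definitions", {
  m <- cm(rbind(c(8, 2), c(4, 4), c(0, 5)))
  st <- ma_stats(m, c("s01", "s02"))
  expect_s3_class(st, "ma_stats")
  expect_equal(st$feature, c("f01", "f02"))  # (0,5) excluded
  expect_equal(unname(st$M), c(2, 0))
  expect_equal(unname(st$A), c(2, 2))
  # baseline member is the per-feature median across all samples
  m3 <- cm(rbind(c(2, 4, 8), c(16, 4, 2)))
  stb <- ma_stats(m3, c("s03", "baseline"))
  expect_equal(unname(stb$M), c(log2(8 / 4), log2(2 / 4)))
  expect_error(ma_stats(m, c("s01", "nope")), "unknown sample")
  expect_error(ma_stats(cm(rbind(c(0, 1))), c("s01", "s02")), "shared positive")
})

test_that("linear-regression normalization removes a constant offset toward the baseline", {
  x <- c(4, 9, 25, 60, 140, 300, 700, 1500)
  m <- cm(cbind(x, x, 4 * x))
  out <- normalize_linear_regression(m)
  # identical-to-baseline samples unchanged
  expect_equal(out$counts[, 1], m$counts[, 1])
  # constant M = 2: corrected values are the geometric mean of sample and baseline
  expect_equal(unname(out$counts[, 3]), 2 * x, tolerance = 1e-9)
  # an exactly linear M(A) trend is reproduced with zero residuals
  lx <- log2(x)
  s3 <- 2^(lx * (1 + 0.05) / (1 - 0.05))
  ml <- cm(cbind(x, x, s3))
  outl <- normalize_linear_regression(ml)
  A <- (log2(s3) + lx) / 2
  expect_equal(unname(outl$counts[, 3]), 2^A, tolerance = 1e-9)
})

test_that("cyclic loess removes global and intensity-dependent disagreement", {
  x <- round(2^seq(3, 12, length.out = 120))
  # global 2^1 shift between two samples
  m <- cm(cbind(x, 2 * x))
  out <- normalize_cyclic_loess(m)
  L <- log2(out$counts + 1)
  expect_lt(abs(median(L[, 2] - L[, 1])), 0.05)
  # identical samples pass through (within the transform round-trip)
  mid <- cm(cbind(x, x, x))
  expect_equal(normalize_cyclic_loess(mid)$counts, mid$counts, tolerance = 1e-6)
  # smooth injected distortion M = g(A) is flattened per A-decile
  A0 <- log2(x + 1)
  g <- 0.5 * sin(pi * (A0 - 3) / 9)
  md <- cm(cbind(x, round(x * 2^g)))
  outd <- normalize_cyclic_loess(md)
  Ld <- log2(outd$counts + 1)
  M <- Ld[, 2] - Ld[, 1]
  A <- (Ld[, 2] + Ld[, 1]) / 2
  dec <- cut(A, quantile(A, 0:10 / 10), include.lowest = TRUE)
  expect_true(all(abs(tapply(M, dec, median)) < 0.1))
  # too few shared-positive features: pair skipped with a warning per cycle
  tiny <- cm(cbind(c(5, 6, 7), c(5, 6, 8)))
  w <- capture_warnings(out_tiny <- normalize_cyclic_loess(tiny))
  expect_true(all(grepl("fewer than 10", w)))
  expect_equal(out_tiny$counts, tiny$counts, tolerance = 1e-9)
})

test_that("quantile normalization equalizes distributions with block-mean ties", {
  m <- cm(cbind(c(1, 3, 5), c(2, 4, 8)))
  q <- normalize_quantile(m)$counts
  expect_equal(unname(q[, 1]), c(1.5, 3.5, 6.5))
  expect_equal(unname(q[, 2]), c(1.5, 3.5, 6.5))
  # ties: both zeros receive the mean of the rank-1 and rank-2 references
  mt <- cm(cbind(c(0, 0, 7), c(1, 2, 3)))
  ref <- rowMeans(cbind(sort(c(0, 0, 7)), sort(c(1, 2, 3))))
  qt <- normalize_quantile(mt)$counts
  expect_equal(unname(qt[, 1]), c(mean(ref[1:2]), mean(ref[1:2]), ref[3]))
  # identical columns unchanged; sorted columns identical in general
  id <- cm(cbind(c(2, 9, 4), c(2, 9, 4)))
  expect_equal(normalize_quantile(id)$counts, id$counts)
  big <- lcg_matrix(50, 4, max = 1e6)  # effectively tie-free
  qb <- normalize_quantile(big)$counts
  srt <- apply(qb, 2, sort)
  expect_equal(srt[, 1], srt[, 2])
  expect_equal(srt[, 1], srt[, 4])
  skip_if_not_installed("limma")
  expect_equal(unname(qb), unname(limma::normalizeQuantiles(big$counts)),
               tolerance = 1e-12)
})

test_that("normalize() dispatch matches direct calls and rejects unknown methods", {
  m <- filter_low_counts(default_dataset(seed = 2)$counts)
  expect_equal(normalize(m, "cpm")$normalized$counts,
               normalize_cpm(m)$normalized$counts)
  ref <- samples(m)[4]
  expect_equal(normalize(m, "tmm", reference = ref)$factors$factors,
               normalize_tmm(m, reference = ref)$factors$factors)
  expect_error(normalize(m, "rpkm"), "valid methods")
  none <- normalize(m, "none")
  expect_equal(none$normalized$counts, m$counts)
  expect_true(all(none$factors$factors == 1))
})

test_that("every method maps identical columns to themselves and preserves shape and sign", {
  # column sums to exactly 1e6 so even the cpm convention is the identity
  # here; 12 positive features so no cyclic-loess pair is skipped
  col <- c(0, 2000, 7000, 30000, 100000, 430000, 301000, 5000, 16000, 59000,
           20000, 18000, 12000)
  stopifnot(sum(col) == 1e6)
  m <- cm(matrix(rep(col, 3), ncol = 3))
  for (meth in normalization_methods()) {
    res <- normalize(m, meth)
    out <- res$normalized
    expect_equal(dim(out$counts), dim(m$counts), label = meth)
    expect_true(all(out$counts >= 0), label = meth)
    expect_equal(out$counts, m$counts, tolerance = 1e-9, label = meth)
    if (!is.null(res$factors))
      expect_equal(unname(res$factors$factors), rep(1, 3), tolerance = 1e-9,
                   label = meth)
  }
})
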