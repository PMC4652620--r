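#' @name normalization
#' @title Count normalization methods
#'
#' @description
#' Eight strategies to remove sample-to-sample technical variation from a
#' count matrix before comparison: four linear scalings (counts-per-million,
#' total-count, upper-quartile, trimmed mean of M-values), the
#' median-of-ratios size factor, two MA-plot regression corrections (linear
#' and cyclic loess) and quantile normalization. Scaling methods return the
#' per-sample factors alongside the normalized matrix; the regression and
#' quantile methods act feature-wise and have no single per-sample factor.
#'
#' All methods preserve the matrix shape and map an all-identical-columns
#' matrix to itself.
NULL

norm_result <- function(m, values, method, factors = NULL, reference = NULL) {
  out <- replace_counts(m, values)
  sf <- NULL
  if (!is.null(factors)) {
    stopifnot(all(is.finite(factors)), all(factors > 0))
    sf <- structure(list(method = method, factors = factors,
                         reference = reference), class = "scaling_factors")
  }
  list(normalized = out, factors = sf)
}

#' @export
print.scaling_factors <- function(x, ...) {
  cat(sprintf("scaling_factors (%s)%s\n", x$method,
              if (is.null(x$reference)) "" else paste0(", reference ", x$reference)))
  print(x$factors)
  invisible(x)
}

check_positive_sums <- function(m) {
  s <- colSums(m$counts)
  if (any(s <= 0))
    stop("zero-sum column: sample ", colnames(m$counts)[which(s <= 0)[1]])
  s
}

#' Counts per million
#'
#' Rescales each sample to a total of one million, the simplest depth
#' adjustment.
#'
#' @param m A `count_matrix` with positive column sums.
#' @return A list with `normalized` (the scaled `count_matrix`) and `factors`
#'   (per-sample multipliers `1e6 / library size`).
#' @export
normalize_cpm <- function(m) {
  s <- check_positive_sums(m)
  d <- 1e6 / s
  norm_result(m, sweep(m$counts, 2, d, `*`), "cpm", d)
}

#' Total-count scaling
#'
#' Rescales every sample to the library size of the baseline sample (the
#' sample with the median library size, see [library_sizes()]): factor
#' `d_i = s_baseline / s_i`.
#'
#' @inheritParams normalize_cpm
#' @return As [normalize_cpm()]; the baseline's factor is exactly 1.
#' @export
normalize_total_count <- function(m) {
  s <- check_positive_sums(m)
  ls <- library_sizes(m)
  d <- ls$s_baseline / s
  norm_result(m, sweep(m$counts, 2, d, `*`), "total_count", d,
              reference = ls$baseline)
}

#' Upper-quartile scaling
#'
#' Scales each sample by its 75th percentile of counts, computed over
#' features expressed somewhere in the matrix (nonzero total), so the mass of
#' zeros does not pin the quantile at 0. Factors are anchored to the
#' geometric mean of the per-sample quartiles and therefore have geometric
#' mean 1.
#'
#' @inheritParams normalize_cpm
#' @return As [normalize_cpm()].
#' @export
normalize_upper_quartile <- function(m) {
  expressed <- rowSums(m$counts) > 0
  q <- apply(m$counts[expressed, , drop = FALSE], 2, stats::quantile,
             probs = 0.75, names = FALSE)
  if (any(q <= 0))
    stop("zero upper quartile in sample ", colnames(m$counts)[which(q <= 0)[1]])
  d <- geomean(q) / q
  norm_result(m, sweep(m$counts, 2, d, `*`), "upper_quartile", d)
}

#' Trimmed mean of M-values (TMM)
#'
#' Estimates a linear scaling factor per sample from a precision-weighted
#' mean of per-feature log fold-changes (M) against a reference sample,
#' after trimming the extremes of M and of average intensity (A).
#'
#' For sample k against reference r, over features positive in both:
#' \deqn{M_i = \log_2\frac{x_{ik}/s_k}{x_{ir}/s_r}, \quad
#'       A_i = \tfrac12 \log_2\left(\frac{x_{ik}}{s_k}\cdot\frac{x_{ir}}{s_r}\right)}
#' with delta-method variance
#' \eqn{v_i = (s_k - x_{ik})/(s_k x_{ik}) + (s_r - x_{ir})/(s_r x_{ir})}.
#' Features in the upper/lower `trim_M/2` quantiles of M or `trim_A/2`
#' quantiles of A are discarded; the factor is
#' \eqn{\log_2 f_k = \sum M_i/v_i \, / \sum 1/v_i}. Factors are rescaled to
#' geometric mean 1 and counts returned as
#' \eqn{x'_{ik} = x_{ik}\,\tilde N/(s_k f_k)} with \eqn{\tilde N} the
#' geometric mean library size, so a normalized sample is on the common
#' effective-depth scale.
#'
#' @param m A `count_matrix` with at least two samples.
#' @param trim_M Total fraction of M-values trimmed (default 0.30).
#' @param trim_A Total fraction of A-values trimmed (default 0.05).
#' @param reference Sample id to normalize against, or `NULL` to pick the
#'   sample whose 75th percentile of depth-scaled counts is closest to the
#'   mean such percentile.
#' @return As [normalize_cpm()]; `factors` are the geometric-mean-1 TMM
#'   factors f.
#' @export
normalize_tmm <- function(m, trim_M = 0.30, trim_A = 0.05, reference = NULL) {
  x <- m$counts
  if (ncol(x) < 2) stop("TMM needs at least two samples")
  s <- check_positive_sums(m)
  if (is.null(reference)) {
    q75 <- apply(sweep(x, 2, s, `/`), 2, stats::quantile, probs = 0.75,
                 names = FALSE)
    reference <- colnames(x)[which.min(abs(q75 - mean(q75)))]
  }
  if (!reference %in% colnames(x)) stop("unknown reference sample: ", reference)
  logf <- vapply(colnames(x), function(k) {
    if (k == reference) return(0)
    tmm_log_factor(x[, k], x[, reference], s[k], s[reference], trim_M, trim_A, k)
  }, numeric(1))
  f <- 2^logf
  f <- f / geomean(f)
  ntilde <- geomean(s)
  norm_result(m, sweep(x, 2, ntilde / (s * f), `*`), "tmm", f,
              reference = reference)
}

tmm_log_factor <- function(xk, xr, sk, sr, trim_M, trim_A, sample_id) {
  pos <- xk > 0 & xr > 0
  if (!any(pos)) {
    warning("no feature positive in both ", sample_id, " and the reference; factor 1")
    return(0)
  }
  xk <- xk[pos]; xr <- xr[pos]
  M <- log2((xk / sk) / (xr / sr))
  A <- 0.5 * log2((xk / sk) * (xr / sr))
  v <- (sk - xk) / (sk * xk) + (sr - xr) / (sr * xr)
  if (length(M) == 1) return(M)
  keepM <- M >= stats::quantile(M, trim_M / 2) & M <= stats::quantile(M, 1 - trim_M / 2)
  keepA <- A >= stats::quantile(A, trim_A / 2) & A <= stats::quantile(A, 1 - trim_A / 2)
  keep <- keepM & keepA
  if (!any(keep)) {
    warning("trimming removed every feature for sample ", sample_id, "; factor 1")
    return(0)
  }
  sum(M[keep] / v[keep]) / sum(1 / v[keep])
}

#' Median-of-ratios size factors
#'
#' The size factor of a sample is the median, over features with no zero
#' anywhere, of the ratio of its count to the feature's geometric mean across
#' samples. Counts are divided by the size factor.
#'
#' @param m A `count_matrix` with at least one all-positive feature.
#' @return A list with `normalized` and `factors`; here `factors` holds the
#'   per-sample multipliers `1 / size factor` so that, as for every scaling
#'   method, normalized counts are `x * factor`. The size factors themselves
#'   are in `factors$size_factors`.
#' @export
normalize_median_ratio <- function(m) {
  x <- m$counts
  allpos <- rowSums(x == 0) == 0
  if (!any(allpos))
    stop("no feature is positive in every sample; filter low counts first")
  lg <- rowMeans(log(x[allpos, , drop = FALSE]))
  sf <- apply(log(x[allpos, , drop = FALSE]) - lg, 2, function(r) exp(stats::median(r)))
  res <- norm_result(m, sweep(x, 2, sf, `/`), "median_ratio", 1 / sf)
  res$factors$size_factors <- sf
  res
}

#' M and A statistics for a sample pair
#'
#' Per-feature log2 ratio M and average log intensity A between two columns,
#' or between a column and the synthetic baseline profile (the per-feature
#' median across all samples). Features with a zero value (after the
#' pseudocount) in either member are excluded so M and A stay finite.
#'
#' @param m A `count_matrix`.
#' @param pair Character vector of length 2; each element a sample id, the
#'   first may be `"baseline"` for the median profile. M is
#'   `log2(first / second)`.
#' @param pseudocount Added to both members before the ratio (default 0).
#' @return A list with `feature`, `M`, `A` and `pair`, class `ma_stats`.
#' @export
ma_stats <- function(m, pair, pseudocount = 0) {
  stopifnot(length(pair) == 2)
  col <- function(id) {
    if (id == "baseline") apply(m$counts, 1, stats::median)
    else if (id %in% colnames(m$counts)) m$counts[, id]
    else stop("unknown sample: ", id)
  }
  x1 <- col(pair[1]) + pseudocount
  x2 <- col(pair[2]) + pseudocount
  keep <- x1 > 0 & x2 > 0
  if (!any(keep)) stop("no shared positive features for pair ",
                       paste(pair, collapse = " vs "))
  structure(list(feature = rownames(m$counts)[keep],
                 M = log2(x1[keep] / x2[keep]),
                 A = 0.5 * log2(x1[keep] * x2[keep]),
                 pair = pair),
            class = "ma_stats")
}

#' Linear-regression (MA-plot) normalization
#'
#' Assumes the systematic bias of a sample against the baseline profile (the
#' per-feature median across samples) is linear in average intensity: fits
#' ordinary least squares M = b0 + b1 A per sample, subtracts the fitted
#' trend from M, and rebuilds the sample's values as `2^(A + M'/2)` with the
#' corrected ratio M'. The baseline profile itself is never altered, so all
#' samples are corrected toward a common anchor. Features excluded from the
#' MA statistics (zero in sample or baseline) pass through unchanged.
#'
#' @param m A `count_matrix`.
#' @return The normalized `count_matrix` (no per-sample scaling factor
#'   exists for this method).
#' @export
normalize_linear_regression <- function(m) {
  out <- m$counts
  for (j in colnames(out)) {
    st <- ma_stats(m, c(j, "baseline"))
    if (length(st$M) < 2) next
    corrected <- if (stats::var(st$A) == 0) st$M - mean(st$M)
                 else stats::residuals(stats::lm(st$M ~ st$A))
    out[st$feature, j] <- 2^(st$A + corrected / 2)
  }
  replace_counts(m, out)
}

#' Cyclic loess normalization
#'
#' Removes intensity-dependent (nonlinear) disagreement between samples. On
#' the log2(x+1) scale, for every unordered sample pair an MA scatter is
#' formed over features positive in both, a lowess smoother c(A) of M on A is
#' fitted, and half the fitted correction is subtracted from one sample and
#' added to the other. Cycling over all pairs is repeated `iterations` times.
#' Results are returned on the count scale (inverse transform, floored at 0).
#'
#' @param m A `count_matrix` with at least two samples.
#' @param span Lowess span (default 0.7).
#' @param iterations Number of full cycles over the sample pairs (default 3).
#' @return The normalized `count_matrix`.
#' @export
normalize_cyclic_loess <- function(m, span = 0.7, iterations = 3) {
  if (ncol(m$counts) < 2) stop("cyclic loess needs at least two samples")
  L <- log2(m$counts + 1)
  n <- ncol(L)
  for (it in seq_len(iterations)) {
    for (j in seq_len(n - 1)) for (k in (j + 1):n) {
      pos <- L[, j] > 0 & L[, k] > 0
      if (sum(pos) < 10) {
        warning(sprintf("pair (%s, %s): fewer than 10 shared-positive features; skipped",
                        colnames(L)[j], colnames(L)[k]))
        next
      }
      M <- L[pos, j] - L[pos, k]
      A <- (L[pos, j] + L[pos, k]) / 2
      c_of_A <- lowess_fit(A, M, span)
      L[pos, j] <- L[pos, j] - c_of_A / 2
      L[pos, k] <- L[pos, k] + c_of_A / 2
    }
  }
  replace_counts(m, pmax(2^L - 1, 0))
}

#' Quantile normalization
#'
#' Forces every sample to share one count distribution: within each column
#' values are ranked and replaced by the across-column mean of the values at
#' that rank; tied values all receive the mean of the reference values of
#' their tied ranks. Output columns have identical sorted values.
#'
#' @param m A `count_matrix` with at least two samples.
#' @return The normalized `count_matrix`.
#' @export
normalize_quantile <- function(m) {
  x <- m$counts
  if (ncol(x) < 2) stop("quantile normalization needs at least two samples")
  ref <- rowMeans(apply(x, 2, sort))
  out <- apply(x, 2, function(col) {
    assigned <- numeric(length(col))
    assigned[order(col)] <- ref
    stats::ave(assigned, col, FUN = mean)
  })
  replace_counts(m, out)
}

#' Normalize a count matrix by name
#'
#' Dispatch over the eight methods plus the raw passthrough `"none"`.
#'
#' @param m A `count_matrix`.
#' @param method One of `"none"`, `"cpm"`, `"total_count"`,
#'   `"upper_quartile"`, `"tmm"`, `"median_ratio"`, `"linear_regression"`,
#'   `"cyclic_loess"`, `"quantile"`.
#' @param ... Passed to the method (e.g. `reference` for `"tmm"`, `span` for
#'   `"cyclic_loess"`).
#' @return A list with `normalized`, `factors` (`NULL` for the regression,
#'   loess and quantile methods, which have no per-sample factor; all 1 for
#'   `"none"`) and `method`.
#' @export
normalize <- function(m, method, ...) {
  methods <- c("none", "cpm", "total_count", "upper_quartile", "tmm",
               "median_ratio", "linear_regression", "cyclic_loess", "quantile")
  if (!method %in% methods)
    stop("unknown method '", method, "'; valid methods: ",
         paste(methods, collapse = ", "))
  res <- switch(method,
    none = norm_result(m, m$counts, "none",
                       stats::setNames(rep(1, ncol(m$counts)), colnames(m$counts))),
    cpm = normalize_cpm(m),
    total_count = normalize_total_count(m),
    upper_quartile = normalize_upper_quartile(m),
    tmm = normalize_tmm(m, ...),
    median_ratio = normalize_median_ratio(m),
    linear_regression = list(normalized = normalize_linear_regression(m), factors = NULL),
    cyclic_loess = list(normalized = normalize_cyclic_loess(m, ...), factors = NULL),
    quantile = list(normalized = normalize_quantile(m), factors = NULL))
  res$method <- method
  res
}

#' Methods available to [normalize()]
#' @return Character vector of method names (excluding the `"none"`
#'   passthrough).
#' @export
normalization_methods <- function() {
  c("cpm", "total_count", "upper_quartile", "tmm", "median_ratio",
    "linear_regression", "cyclic_loess", "quantile")
}

#' Write per-sample scaling factors as TSV
#' @param factors A `scaling_factors` object.
#' @param path Output path.
#' @param header Optional comment lines.
#' @return Invisibly, `path`.
#' @export
write_factors <- function(factors, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  writeLines("sample\tmethod\tfactor", con)
  writeLines(paste(names(factors$factors), factors$method,
                   format(factors$factors, trim = TRUE, digits = 15),
                   sep = "\t"), con)
  invisible(path)
}
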