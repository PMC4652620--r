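#' Relative log expression (RLE)
#'
#' For every cell, the log2(x+1) value minus the feature's median log2(x+1)
#' across samples. Well-normalized replicate-like samples have RLE
#' distributions centered at zero.
#'
#' @param m A `count_matrix` with at least two samples.
#' @return A list with `rle` (features x samples matrix) and
#'   `sample_quartiles` (5 x samples matrix of boxplot quartiles: min, Q1,
#'   median, Q3, max).
#' @export
rle_stats <- function(m) {
  if (ncol(m$counts) < 2) stop("RLE needs at least two samples")
  L <- log2(m$counts + 1)
  r <- L - apply(L, 1, stats::median)
  q <- apply(r, 2, stats::quantile, probs = c(0, 0.25, 0.5, 0.75, 1),
             names = FALSE)
  rownames(q) <- c("min", "q1", "median", "q3", "max")
  list(rle = r, sample_quartiles = q)
}

#' Variance change after normalization
#'
#' Per-feature variance of log2(x+1) across samples, before and after
#' normalization, and the share of features whose variance strictly
#' decreased — the headline "% with lower variance" comparison.
#'
#' @param raw,norm `count_matrix` objects sharing features and samples.
#' @param background_only Restrict `fraction_lower` to non-spike-in features
#'   (default `TRUE`), since spike-ins vary by design.
#' @return A list with `table` (data frame: feature, is_spikein, var_raw,
#'   var_norm) and `fraction_lower` (share with `var_norm < var_raw`, strict).
#' @export
variance_summary <- function(raw, norm, background_only = TRUE) {
  stopifnot(identical(features(raw), features(norm)),
            identical(samples(raw), samples(norm)))
  vr <- apply(log2(raw$counts + 1), 1, stats::var)
  vn <- apply(log2(norm$counts + 1), 1, stats::var)
  tab <- data.frame(feature = features(raw), is_spikein = raw$is_spikein,
                    var_raw = vr, var_norm = vn, row.names = NULL)
  sel <- if (background_only) !tab$is_spikein else rep(TRUE, nrow(tab))
  list(table = tab, fraction_lower = mean(tab$var_norm[sel] < tab$var_raw[sel]))
}

#' Variance-ratio versus abundance trend
#'
#' Plots-ready mean-variance dependency: for each feature, the log2 ratio of
#' normalized to raw variance against its mean raw log2(x+1) abundance, with
#' a lowess smoother revealing intensity-dependent variance changes. Points
#' below y = 0 have decreased variance.
#'
#' @inheritParams variance_summary
#' @param span Lowess span for the smoother (default 2/3).
#' @return Data frame with `feature`, `mean_log_count`, `log2_var_ratio` and
#'   `smooth` (`NA` when fewer than 10 usable features). Features with zero
#'   raw variance, or a non-finite ratio, are excluded.
#' @export
variance_ratio_trend <- function(raw, norm, span = 2/3) {
  stopifnot(identical(features(raw), features(norm)),
            identical(samples(raw), samples(norm)))
  vr <- apply(log2(raw$counts + 1), 1, stats::var)
  vn <- apply(log2(norm$counts + 1), 1, stats::var)
  x <- rowMeans(log2(raw$counts + 1))
  y <- log2(vn / vr)
  keep <- vr > 0 & is.finite(y)
  out <- data.frame(feature = features(raw)[keep], mean_log_count = x[keep],
                    log2_var_ratio = y[keep], smooth = NA_real_,
                    row.names = NULL)
  if (nrow(out) >= 10)
    out$smooth <- lowess_fit(out$mean_log_count, out$log2_var_ratio, span)
  out
}

#' Dilution-series bias regression
#'
#' For each spike-in, ordinary least squares of log2(count + 1) on
#' log2(amount) over the samples where the designed amount is positive (the
#' 0-amol well is excluded). A slope of 1 means counts track the spiked
#' amounts; the fit's R-squared measures how well the series behaves.
#'
#' @param norm A `count_matrix` containing the spike-in rows (by design
#'   spike-in id).
#' @param design A `spikein_design`.
#' @param exclude Spike-in ids to skip (e.g. a series known to be corrupted).
#' @param pseudocount Added to counts before the log (default 1, for
#'   zero-safety at the lowest dilutions; set to 0 to fit the plain
#'   log-log model on strictly positive series). The pseudocount flattens
#'   the bottom of a dilution series, so slopes on weakly captured spike-ins
#'   are attenuated relative to the pseudocount-free model.
#' @return Data frame with one row per fitted series: `spikein`, `beta0`,
#'   `beta1`, `r_squared`, `n_points`, `degenerate` (`TRUE` when all counts in
#'   the series are equal; then slope and R-squared are 0).
#' @export
fit_bias_model <- function(norm, design, exclude = character(), pseudocount = 1) {
  ids <- setdiff(colnames(design$assignment), exclude)
  ids <- intersect(ids, features(norm))
  if (!length(ids)) stop("no spike-in rows found in the matrix")
  do.call(rbind, lapply(ids, function(s) {
    amt <- design$assignment[, s]
    use <- amt > 0
    use <- use[samples(norm)]
    x <- log2(amt[samples(norm)][use])
    y <- log2(norm$counts[s, use] + pseudocount)
    if (any(!is.finite(y))) stop("zero count with pseudocount 0 in series ", s)
    if (sum(use) < 2) stop("fewer than 2 positive-amount points for ", s)
    if (stats::var(y) == 0)
      return(data.frame(spikein = s, beta0 = mean(y), beta1 = 0,
                        r_squared = 0, n_points = sum(use), degenerate = TRUE))
    fit <- stats::lm(y ~ x)
    data.frame(spikein = s, beta0 = unname(stats::coef(fit)[1]),
               beta1 = unname(stats::coef(fit)[2]),
               r_squared = stats::cor(y, stats::fitted(fit))^2,
               n_points = sum(use), degenerate = FALSE)
  }))
}

#' Pairwise log2 fold-changes
#'
#' `log2((x_a + 1)/(x_b + 1))` per feature for each requested sample pair.
#'
#' @param norm A `count_matrix` with at least two samples.
#' @param reference A sample id to compare every other sample against, or
#'   `NULL` (default) for all unordered pairs.
#' @return Data frame with `feature`, `sample_a`, `sample_b`, `log2fc`
#'   (oriented a over b).
#' @export
pairwise_log_ratios <- function(norm, reference = NULL) {
  ids <- samples(norm)
  if (length(ids) < 2) stop("need at least two samples")
  L <- log2(norm$counts + 1)
  pairs <- if (is.null(reference)) utils::combn(ids, 2)
           else rbind(setdiff(ids, reference), reference)
  do.call(rbind, lapply(seq_len(ncol(pairs)), function(p) {
    a <- pairs[1, p]; b <- pairs[2, p]
    data.frame(feature = rownames(L), sample_a = a, sample_b = b,
               log2fc = L[, a] - L[, b], row.names = NULL)
  }))
}

#' Precision-recall curve for differential-expression calls
#'
#' Ground-truth positives are spike-ins whose nominal fold-change meets the
#' differential-expression threshold (or is infinite, i.e. present versus a
#' 0-amol well); negatives are the constant background. Sub-threshold
#' spike-ins, which are neither truly differential nor truly constant, are
#' excluded. The decision statistic |estimated log2 FC| is swept over every
#' observed unique value (plus +Inf); at each cutoff precision = TP/(TP+FP)
#' — 1 by convention when nothing is called — and recall = TP/P. The area
#' is the step-wise integral of precision over recall.
#'
#' @param estimated Numeric vector of estimated log2 fold-changes, one per
#'   feature (absolute values are used).
#' @param truth Data frame as from [pair_truth()] (columns `is_spikein`,
#'   `nominal_log2fc`, `infinite`), aligned with `estimated`.
#' @param fc_threshold Fold-change (linear scale) defining a true positive
#'   (default 2, i.e. |nominal log2 FC| >= 1).
#' @return Class `pr_curve`: list with `thresholds` (descending),
#'   `precision`, `recall`, `auc`, `n_positive`, `n_negative`.
#' @export
pr_curve <- function(estimated, truth, fc_threshold = 2) {
  stopifnot(length(estimated) == nrow(truth))
  pos <- truth$is_spikein &
    (truth$infinite | abs(truth$nominal_log2fc) >= log2(fc_threshold))
  neg <- !truth$is_spikein
  keep <- pos | neg
  score <- abs(estimated)[keep]
  pos <- pos[keep]
  P <- sum(pos)
  if (P == 0) stop("no true positives in the truth set; degenerate pair")
  ord <- order(score, decreasing = TRUE)
  score <- score[ord]; pos <- pos[ord]
  tp <- cumsum(pos)
  n_called <- seq_along(score)
  # collapse tied scores: a threshold admits every value >= it
  last <- !duplicated(score, fromLast = TRUE)
  thresholds <- c(Inf, score[last])
  precision <- c(1, (tp / n_called)[last])
  recall <- c(0, (tp / P)[last])
  auc <- sum(diff(recall) * precision[-1])
  structure(list(thresholds = thresholds, precision = precision,
                 recall = recall, auc = auc,
                 n_positive = P, n_negative = sum(!pos)),
            class = "pr_curve")
}

#' @export
print.pr_curve <- function(x, ...) {
  cat(sprintf("pr_curve: %d thresholds, P=%d N=%d, AUC=%.4f\n",
              length(x$thresholds), x$n_positive, x$n_negative, x$auc))
  invisible(x)
}

#' Pooled precision-recall over all sample pairs of a dataset
#'
#' Convenience wrapper: computes [pairwise_log_ratios()] on a normalized
#' matrix, aligns each pair with the dataset's ground truth, and evaluates a
#' single PR curve over the pooled feature-pair observations.
#'
#' @param norm A normalized `count_matrix` over the dataset's samples.
#' @param ds The `sim_dataset` providing the truth.
#' @param fc_threshold As in [pr_curve()].
#' @return A `pr_curve`.
#' @export
pooled_pr <- function(norm, ds, fc_threshold = 2) {
  fc <- pairwise_log_ratios(norm)
  truth <- pooled_truth(ds, fc)
  pr_curve(fc$log2fc, truth, fc_threshold)
}

# Align pair_truth rows with a pairwise_log_ratios table (features must be a
# subset of the dataset's features, e.g. after filtering).
pooled_truth <- function(ds, fc) {
  key <- paste(fc$sample_a, fc$sample_b)
  do.call(rbind, lapply(unique(key), function(k) {
    p <- strsplit(k, " ")[[1]]
    tr <- pair_truth(ds, p[1], p[2])
    tr[match(fc$feature[key == k], tr$feature), ]
  }))
}

#' Absolute bias of fold-change estimates
#'
#' The per-observation difference between estimated and nominal log2
#' fold-changes; an unbiased pipeline centers this at zero. Pairs with an
#' infinite nominal fold-change (0-amol wells) have no finite truth and are
#' excluded.
#'
#' @param estimated Numeric vector of estimated log2 fold-changes.
#' @param truth Aligned truth data frame (columns `nominal_log2fc`,
#'   `infinite`) as from [pair_truth()].
#' @return A list with `bias` (the per-observation differences), `median`,
#'   `q1`, `q3` and `n`.
#' @export
absolute_bias <- function(estimated, truth) {
  stopifnot(length(estimated) == nrow(truth))
  keep <- !truth$infinite
  b <- estimated[keep] - truth$nominal_log2fc[keep]
  q <- stats::quantile(b, c(0.25, 0.5, 0.75), names = FALSE)
  list(bias = b, median = q[2], q1 = q[1], q3 = q[3], n = length(b))
}

#' Fold-change concordance between methods
#'
#' Spearman correlations between the pooled fold-change estimates of several
#' normalization methods, clustered by complete linkage on the Euclidean
#' distances between the correlation matrix rows — methods that agree merge
#' early in the dendrogram.
#'
#' @param fc_vectors Named list (one element per method) of numeric vectors
#'   over a shared feature-pair index.
#' @return A list with `correlation` (Spearman matrix) and `clustering`
#'   (an `hclust` object: merge order and heights).
#' @export
fc_concordance <- function(fc_vectors) {
  stopifnot(length(fc_vectors) >= 2)
  lens <- lengths(fc_vectors)
  stopifnot(all(lens == lens[1]))
  const <- vapply(fc_vectors, function(v) stats::var(v) == 0, logical(1))
  if (any(const))
    stop("constant fold-change vector for method: ",
         paste(names(fc_vectors)[const], collapse = ", "))
  mat <- do.call(cbind, fc_vectors)
  co <- stats::cor(mat, method = "spearman")
  hc <- stats::hclust(stats::dist(co, method = "euclidean"), method = "complete")
  list(correlation = co, clustering = hc)
}
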