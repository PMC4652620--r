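#' Construct a count matrix
#'
#' The central container of the package: a features x samples grid of
#' non-negative counts with a per-feature spike-in flag. Raw inputs hold
#' integers; normalized outputs may be fractional.
#'
#' @param counts Numeric matrix, features in rows and samples in columns,
#'   with unique rownames (feature ids) and colnames (sample ids). All values
#'   must be non-negative and non-missing.
#' @param is_spikein Logical vector, one flag per feature, marking spike-in
#'   sequences. Defaults to all `FALSE`.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   and `is_spikein`.
#' @export
count_matrix <- function(counts, is_spikein = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      (ncol(counts) > 0 && is.null(colnames(counts))))
    stop("counts must have feature rownames and sample colnames")
  if (is.null(rownames(counts))) rownames(counts) <- character(0)
  if (anyDuplicated(rownames(counts)))
    stop("duplicate feature id: ",
         rownames(counts)[anyDuplicated(rownames(counts))])
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample id: ",
         colnames(counts)[anyDuplicated(colnames(counts))])
  if (anyNA(counts)) stop("counts contain missing values")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at feature '%s', sample '%s'",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]))
  }
  if (is.null(is_spikein)) is_spikein <- rep(FALSE, nrow(counts))
  stopifnot(is.logical(is_spikein), length(is_spikein) == nrow(counts))
  structure(list(counts = counts, is_spikein = is_spikein),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d features x %d samples (%d spike-ins)\n",
              nrow(x$counts), ncol(x$counts), sum(x$is_spikein)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Feature and sample ids of a count matrix
#' @param m A `count_matrix`.
#' @return Character vector of ids.
#' @export
features <- function(m) rownames(m$counts)

#' @rdname features
#' @export
samples <- function(m) colnames(m$counts)

# Replace the values grid, keeping dimnames and spike-in flags.
replace_counts <- function(m, values) {
  dimnames(values) <- dimnames(m$counts)
  count_matrix(values, m$is_spikein)
}

#' Read a count matrix from TSV
#'
#' Expects a header row of sample ids, a first column of feature ids and
#' non-negative numeric cells. Lines starting with `#` are ignored, so files
#' written by [write_counts()] round-trip.
#'
#' @param path Path to the tab-separated file.
#' @param spikein_prefix Feature-id prefix marking spike-in rows (the
#'   convention of *A. thaliana* spike-ins in a human background gives the
#'   default `"ath-"`); `NULL` disables flagging.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, spikein_prefix = "ath-") {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           comment.char = "#", check.names = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 2) stop("malformed header: need feature column plus >=1 sample")
  ids <- raw[[1]]
  if (anyDuplicated(ids))
    stop("duplicate feature id: ", ids[anyDuplicated(ids)])
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell '%s' at feature '%s', sample '%s'",
                 vals[bad[1], bad[2]], ids[bad[1]], colnames(vals)[bad[2]]))
  }
  if (any(num < 0)) {
    bad <- which(num < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at feature '%s', sample '%s'",
                 ids[bad[1]], colnames(vals)[bad[2]]))
  }
  rownames(num) <- ids
  colnames(num) <- colnames(vals)
  flag <- if (is.null(spikein_prefix)) rep(FALSE, length(ids))
          else startsWith(ids, spikein_prefix)
  count_matrix(num, flag)
}

#' Write a count matrix as TSV
#'
#' @param m A `count_matrix`.
#' @param path Output path.
#' @param header Optional character vector of comment lines (written with a
#'   leading `#`).
#' @return Invisibly, `path`.
#' @export
write_counts <- function(m, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  writeLines(paste(c("feature", colnames(m$counts)), collapse = "\t"), con)
  body <- apply(m$counts, 1, function(r)
    paste(format(r, trim = TRUE, scientific = FALSE, digits = 15), collapse = "\t"))
  writeLines(paste(rownames(m$counts), body, sep = "\t"), con)
  invisible(path)
}

#' Filter features with low counts
#'
#' Keeps features observed at `min_count` or more in at least
#' `ceiling(min_fraction * n_samples)` samples; both boundaries are
#' inclusive, so with defaults a feature needs >= 5 counts in >= 25% of
#' samples to survive.
#'
#' @param m A `count_matrix`.
#' @param min_count Minimum count per qualifying sample (default 5).
#' @param min_fraction Minimum fraction of samples that must qualify
#'   (default 0.25).
#' @return The filtered `count_matrix`, feature order preserved.
#' @export
filter_low_counts <- function(m, min_count = 5, min_fraction = 0.25) {
  stopifnot(min_fraction > 0, min_fraction <= 1)
  need <- ceiling(min_fraction * ncol(m$counts))
  keep <- rowSums(m$counts >= min_count) >= need
  if (!any(keep)) warning("no feature passes the low-count filter")
  count_matrix(m$counts[keep, , drop = FALSE], m$is_spikein[keep])
}

#' Log2 transform with pseudocount
#'
#' Maps every value v to log2(v + 1); zeros stay zero.
#'
#' @param m A `count_matrix`.
#' @return A `count_matrix` of transformed values.
#' @export
log2_plus_one <- function(m) replace_counts(m, log2(m$counts + 1))

#' Library sizes and baseline sample
#'
#' Column sums plus the baseline (reference) sample, defined as the sample
#' with the median library size. For an even number of samples the smaller
#' of the two middle values is taken, ties broken by the lexicographically
#' smallest sample id, so the baseline is always an actual sample.
#'
#' @param m A `count_matrix`.
#' @return A list with `sizes` (named numeric), `baseline` (sample id) and
#'   `s_baseline`.
#' @export
library_sizes <- function(m) {
  s <- colSums(m$counts)
  ord <- order(s, names(s), method = "radix")
  mid <- ord[ceiling(length(s) / 2)]
  list(sizes = s, baseline = names(s)[mid], s_baseline = unname(s[mid]))
}

#' Downsample columns to a common depth
#'
#' Draws exactly `depth` reads per sample without replacement (multivariate
#' hypergeometric per column), so every output column sum equals `depth` and
#' no cell exceeds its original value. Requires integral counts: normalized
#' matrices are refused.
#'
#' @param m A `count_matrix` of integer counts.
#' @param depth Target reads per sample; at most the smallest column sum.
#' @param seed Integer seed making the draw reproducible.
#' @return The downsampled `count_matrix`.
#' @export
downsample <- function(m, depth, seed) {
  x <- m$counts
  if (any(x != round(x)))
    stop("downsample requires integral counts; normalized matrices are refused")
  s <- colSums(x)
  if (any(s < depth)) {
    bad <- colnames(x)[which(s < depth)[1]]
    stop(sprintf("depth %d exceeds the %s column sum (%d)",
                 as.integer(depth), bad, as.integer(s[bad])))
  }
  out <- with_seed(seed, apply(x, 2, rmvhyper_col, k = depth))
  replace_counts(m, out)
}

# One multivariate hypergeometric draw by sequential conditioning:
# cell i receives Hypergeometric(x_i, remaining total, remaining draw).
rmvhyper_col <- function(x, k) {
  out <- numeric(length(x))
  rest <- sum(x)
  left <- k
  for (i in seq_along(x)) {
    if (left == 0) break
    rest <- rest - x[i]
    out[i] <- stats::rhyper(1, m = x[i], n = rest, k = left)
    left <- left - out[i]
  }
  out
}
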