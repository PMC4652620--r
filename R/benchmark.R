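#' @name benchmark
#' @title End-to-end spike-in benchmark
#'
#' @description
#' The full recipe — simulate (or load) counts, filter low counts, normalize
#' by every requested method, evaluate variance, bias and precision-recall —
#' with TSV writers whose outputs carry a comment header recording the
#' package version, the call and the seed.
NULL

output_header <- function(call_label, seed) {
  c(sprintf("spikenorm %s", as.character(utils::packageVersion("spikenorm"))),
    call_label,
    sprintf("seed: %s", seed))
}

write_tsv_table <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  writeLines(paste(colnames(df), collapse = "\t"), con)
  if (nrow(df)) {
    rows <- do.call(paste, c(lapply(df, function(x)
      if (is.numeric(x)) format(x, trim = TRUE, digits = 15, scientific = FALSE)
      else as.character(x)), sep = "\t"))
    writeLines(rows, con)
  }
  invisible(path)
}

#' Read a TSV table written by this package
#'
#' Skips `#` comment headers; used by the metric writers' round-trips.
#' @param path File path.
#' @return A data frame.
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    comment.char = "#", check.names = FALSE)
}

#' Simulate a dataset and write it to disk
#'
#' Writes the count matrix, the spike-in truth table, the design and a
#' config echo under `dir`. Byte-identical for a fixed config (seed
#' included), so reruns are reproducible.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if missing).
#' @param design A `spikein_design` (default 12x12 cyclic).
#' @return Invisibly, the `sim_dataset`.
#' @export
simulate_to_files <- function(cfg = sim_config(), dir = ".",
                              design = make_latin_square_design()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ds <- simulate_dataset(cfg, design)
  hdr <- output_header("simulate", cfg$seed)
  write_counts(ds$counts, file.path(dir, "counts.tsv"), header = hdr)
  truth <- ds$truth
  names(truth)[names(truth) == "feature"] <- "spikein_id"
  write_tsv_table(truth, file.path(dir, "truth.tsv"), header = hdr)
  a <- design$assignment
  design_long <- data.frame(sample = rownames(a)[row(a)],
                            spikein = colnames(a)[col(a)],
                            amount_amol = as.vector(a))
  write_tsv_table(design_long, file.path(dir, "design.tsv"), header = hdr)
  cfg_lines <- vapply(names(unclass(cfg)), function(k)
    paste0(k, " = ", paste(format(cfg[[k]]), collapse = ",")), character(1))
  writeLines(c(paste0("# ", hdr), cfg_lines), file.path(dir, "config.txt"))
  invisible(ds)
}

#' Downsample a count TSV to a common depth
#'
#' @param counts_path Input count TSV.
#' @param depth Target per-sample depth.
#' @param seed Integer seed.
#' @param out Output path.
#' @return Invisibly, `out`.
#' @export
downsample_file <- function(counts_path, depth, seed, out) {
  m <- read_counts(counts_path)
  d <- downsample(m, depth, seed)
  write_counts(d, out, header = output_header(
    sprintf("downsample %s depth=%d", counts_path, as.integer(depth)), seed))
  invisible(out)
}

#' Run the spike-in benchmark over a set of normalization methods
#'
#' For each method: normalize the (filtered) counts, then compute the
#' variance summary against the raw matrix, the dilution-series bias fits,
#' the absolute fold-change bias over all sample pairs, and the pooled
#' precision-recall curve. Returns everything plus a one-row-per-method
#' summary table (fraction of background features with lower variance,
#' median dilution slope, median R-squared, pooled PR area, median absolute
#' bias).
#'
#' @param ds A `sim_dataset` (or a list with elements `counts`, `design`,
#'   `truth` in the same shapes).
#' @param methods Character vector of methods for [normalize()]; default all
#'   eight plus the raw `"none"` passthrough.
#' @param filter Apply [filter_low_counts()] first (default `TRUE`).
#' @param min_count,min_fraction Filter parameters.
#' @param fc_threshold Differential-expression truth threshold for the PR
#'   curve (default 2-fold).
#' @param exclude_spikeins Spike-in ids excluded from the bias regression.
#' @return Class `benchmark_result`: list with `summary` (data frame),
#'   `per_method` (named list holding `normalized`, `factors`,
#'   `variance`, `bias_fits`, `abs_bias`, `pr`) and `raw` (the filtered
#'   input matrix).
#' @export
run_benchmark <- function(ds, methods = c("none", normalization_methods()),
                          filter = TRUE, min_count = 5, min_fraction = 0.25,
                          fc_threshold = 2, exclude_spikeins = character()) {
  raw <- ds$counts
  if (filter) raw <- filter_low_counts(raw, min_count, min_fraction)
  fc_raw <- pairwise_log_ratios(raw)
  truth <- pooled_truth(ds, fc_raw)
  per_method <- lapply(methods, function(meth) {
    res <- normalize(raw, meth)
    norm <- res$normalized
    vs <- variance_summary(raw, norm)
    bias_fits <- fit_bias_model(norm, ds$design, exclude = exclude_spikeins)
    fc <- pairwise_log_ratios(norm)
    ab <- absolute_bias(fc$log2fc, truth)
    pr <- pr_curve(fc$log2fc, truth, fc_threshold)
    list(normalized = norm, factors = res$factors, variance = vs,
         bias_fits = bias_fits, abs_bias = ab, pr = pr, log2fc = fc$log2fc)
  })
  names(per_method) <- methods
  summary <- do.call(rbind, lapply(methods, function(meth) {
    pm <- per_method[[meth]]
    ok <- !pm$bias_fits$degenerate
    data.frame(method = meth,
               fraction_lower_variance = pm$variance$fraction_lower,
               median_beta1 = stats::median(pm$bias_fits$beta1[ok]),
               median_r_squared = stats::median(pm$bias_fits$r_squared[ok]),
               pr_auc = pm$pr$auc,
               median_abs_bias = pm$abs_bias$median)
  }))
  structure(list(summary = summary, per_method = per_method, raw = raw),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("benchmark_result over", nrow(x$summary), "methods\n")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write benchmark outputs to a directory
#'
#' One normalized matrix, factor table (when the method has factors), bias
#' fits and PR curve per method, plus the cross-method summary TSV and the
#' fold-change concordance matrix. Every file starts with a version/seed
#' header.
#'
#' @param bench A `benchmark_result`.
#' @param dir Output directory.
#' @param seed Seed recorded in the file headers.
#' @return Invisibly, `dir`.
#' @export
write_benchmark <- function(bench, dir, seed = NA) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (meth in names(bench$per_method)) {
    pm <- bench$per_method[[meth]]
    hdr <- output_header(paste("benchmark method", meth), seed)
    write_counts(pm$normalized, file.path(dir, paste0("normalized_", meth, ".tsv")), hdr)
    if (!is.null(pm$factors))
      write_factors(pm$factors, file.path(dir, paste0("factors_", meth, ".tsv")), hdr)
    write_tsv_table(pm$bias_fits, file.path(dir, paste0("bias_", meth, ".tsv")), hdr)
    pr_df <- data.frame(threshold = pm$pr$thresholds,
                        precision = pm$pr$precision, recall = pm$pr$recall)
    write_tsv_table(pr_df, file.path(dir, paste0("pr_", meth, ".tsv")), hdr)
  }
  fcs <- lapply(bench$per_method, `[[`, "log2fc")
  conc <- fc_concordance(fcs)
  co <- data.frame(method = rownames(conc$correlation), conc$correlation,
                   check.names = FALSE)
  write_tsv_table(co, file.path(dir, "concordance.tsv"),
                  output_header("benchmark concordance", seed))
  write_tsv_table(bench$summary, file.path(dir, "summary.tsv"),
                  output_header("benchmark summary", seed))
  invisible(dir)
}
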