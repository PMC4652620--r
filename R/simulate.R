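#' The dilution concentration series (attomoles)
#'
#' Twelve amounts spanning zero and a ~2- to 4-fold ladder up to 3276.8 amol,
#' the series used in the cyclic Latin-Square spike-in experiment this
#' package emulates.
#'
#' @return Numeric vector of 12 amounts in amol.
#' @export
dilution_series <- function() {
  c(0, 0.1, 0.2, 0.8, 1.6, 6.4, 12.8, 51.2, 102.4, 409.6, 819.2, 3276.8)
}

#' Cyclic Latin-Square spike-in design
#'
#' Assigns `n` concentrations to `n` samples x `n` spike-ins cyclically:
#' sample i, spike-in j receives `concentrations[(i + j - 2) %% n + 1]`, so
#' each amount appears exactly once per row (sample) and once per column
#' (spike-in).
#'
#' @param n Order of the square (default 12).
#' @param concentrations Distinct non-negative amounts in amol, length `n`.
#' @return Class `spikein_design`: list with `n`, `concentrations` and
#'   `assignment` (samples x spike-ins matrix of amounts).
#' @export
make_latin_square_design <- function(n = 12, concentrations = dilution_series()) {
  stopifnot(length(concentrations) == n, all(concentrations >= 0))
  if (anyDuplicated(concentrations)) stop("concentrations must be distinct")
  a <- outer(seq_len(n) - 1, seq_len(n) - 1, function(i, j) (i + j) %% n + 1)
  assignment <- matrix(concentrations[a], n, n,
                       dimnames = list(sample = sprintf("S%02d", seq_len(n)),
                                       spikein = sprintf("ath-spike%02d", seq_len(n))))
  structure(list(n = n, concentrations = concentrations,
                 assignment = assignment),
            class = "spikein_design")
}

#' @export
print.spikein_design <- function(x, ...) {
  cat(sprintf("spikein_design: %d x %d cyclic Latin Square, %s amol\n",
              x$n, x$n, paste(range(x$concentrations), collapse = "-")))
  invisible(x)
}

#' Simulation configuration
#'
#' Parameters of the synthetic spike-in experiment. Defaults describe the
#' reference scenario: 500 background miRNAs with log-normal relative
#' abundances, 12 samples at an expected background depth of 2e5 reads,
#' negative-binomial counts with dispersion 0.05, and spike-in capture
#' efficiencies of about 30 expected counts per amol at the reference depth.
#'
#' @param n_background Number of background (non-spike-in) features.
#' @param depths Expected background reads per sample; a scalar is recycled
#'   to the number of samples, `NULL` derives depths from `variable_depth`.
#' @param abundance_meanlog,abundance_sdlog Log-normal parameters of the
#'   background relative abundances (only ratios matter; shares are
#'   renormalized to sum to 1).
#' @param dispersion Negative-binomial dispersion phi >= 0; 0 gives Poisson
#'   counts.
#' @param kappa_per_amol Expected spike-in counts per amol at the reference
#'   depth (geometric mean of the capture efficiencies).
#' @param kappa_sdlog Log-sd of per-spike-in capture efficiencies kappa_s
#'   (one value per spike-in, shared across samples, so the true dilution
#'   slope is exactly 1).
#' @param variable_depth If `TRUE` (and `depths` is `NULL`), per-sample
#'   depths are drawn uniformly between 1e5 and 5e5 instead of being equal.
#' @param composition_fraction,composition_fold,composition_samples A
#'   composition-bias scenario: the chosen fraction of background features —
#'   the most abundant ones, since composition bias is driven by features
#'   that consume sequencing real estate — is multiplied by
#'   `composition_fold` in the affected samples (default: the second half of
#'   the samples). Fraction 0 or fold 1 disables the scenario. These features
#'   keep nominal truth 0: they model unannotated asymmetric expression
#'   contaminating the null, exactly what defeats total-count scaling.
#' @param intensity_amplitude,intensity_samples An intensity-dependent
#'   distortion: expected counts in the affected samples are multiplied by
#'   `2^g(A)` where `A = log2(expected count + 1)` and
#'   `g(A) = amplitude * sin(pi * A / 8)`, a smooth bounded warp of the MA
#'   trend. Amplitude 0 disables it.
#' @param seed Integer seed; every draw in the simulator flows from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_background = 500,
                       depths = NULL,
                       abundance_meanlog = 0,
                       abundance_sdlog = 1.5,
                       dispersion = 0.05,
                       kappa_per_amol = 30,
                       kappa_sdlog = 0.5,
                       variable_depth = FALSE,
                       composition_fraction = 0,
                       composition_fold = 1,
                       composition_samples = NULL,
                       intensity_amplitude = 0,
                       intensity_samples = NULL,
                       seed = 1L) {
  stopifnot(n_background >= 1, abundance_sdlog > 0, dispersion >= 0,
            kappa_per_amol > 0, kappa_sdlog >= 0,
            composition_fraction >= 0, composition_fraction < 1,
            composition_fold > 0)
  structure(list(n_background = n_background, depths = depths,
                 abundance_meanlog = abundance_meanlog,
                 abundance_sdlog = abundance_sdlog,
                 dispersion = dispersion,
                 kappa_per_amol = kappa_per_amol, kappa_sdlog = kappa_sdlog,
                 variable_depth = variable_depth,
                 composition_fraction = composition_fraction,
                 composition_fold = composition_fold,
                 composition_samples = composition_samples,
                 intensity_amplitude = intensity_amplitude,
                 intensity_samples = intensity_samples,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Per-sample expected depths. Drawn under a seed offset of their own so the
# background and spike-in generators see identical depths.
#' Canonical benchmark scenarios
#'
#' The two study conditions evaluated throughout the package: `reference` —
#' equal expected depths, no bias scenario, where every scaling method should
#' roughly agree — and `variable_depth_composition` — per-sample depths drawn
#' from 1e5-5e5 with a 2% minority of the most abundant background features
#' 8-fold up in half the samples, the regime that separates
#' composition-robust scalings (TMM, upper-quartile, median-of-ratios) from
#' total-count-based ones.
#'
#' @param scenario One of `"reference"`, `"variable_depth_composition"`.
#' @param seed Integer seed.
#' @return A [sim_config()].
#' @export
scenario_config <- function(scenario = c("reference", "variable_depth_composition"),
                            seed = 1L) {
  switch(match.arg(scenario),
         reference = sim_config(seed = seed),
         variable_depth_composition = sim_config(
           variable_depth = TRUE, composition_fraction = 0.02,
           composition_fold = 8, seed = seed))
}

resolve_depths <- function(cfg, n_samples) {
  if (!is.null(cfg$depths)) {
    d <- rep_len(cfg$depths, n_samples)
  } else if (cfg$variable_depth) {
    d <- with_seed(cfg$seed + 2L, stats::runif(n_samples, 1e5, 5e5))
  } else {
    d <- rep(2e5, n_samples)
  }
  stopifnot(all(d > 0))
  d
}

nb_draw <- function(mu, dispersion) {
  out <- if (dispersion == 0) stats::rpois(length(mu), mu)
         else stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
  out[mu == 0] <- 0
  out
}

default_affected <- function(ids, chosen) {
  if (!is.null(chosen)) chosen else ids[seq_along(ids) > length(ids) / 2]
}

# Expected background counts (features x samples) before count noise.
background_means <- function(cfg, n_samples, sample_ids) {
  share <- stats::rlnorm(cfg$n_background, cfg$abundance_meanlog, cfg$abundance_sdlog)
  share <- share / sum(share)
  depths <- resolve_depths(cfg, n_samples)
  mu <- outer(share, depths)
  dimnames(mu) <- list(sprintf("hsa-bg%04d", seq_len(cfg$n_background)), sample_ids)
  if (cfg$composition_fraction > 0 && cfg$composition_fold != 1) {
    # Composition bias: the most abundant features change, consuming
    # sequencing real estate in the affected samples.
    hit <- order(share, decreasing = TRUE)[
      seq_len(max(1, round(cfg$composition_fraction * cfg$n_background)))]
    aff <- default_affected(sample_ids, cfg$composition_samples)
    mu[hit, aff] <- mu[hit, aff] * cfg$composition_fold
  }
  if (cfg$intensity_amplitude != 0) {
    aff <- default_affected(sample_ids, cfg$intensity_samples)
    A <- log2(mu[, aff, drop = FALSE] + 1)
    mu[, aff] <- mu[, aff, drop = FALSE] * 2^(cfg$intensity_amplitude * sin(pi * A / 8))
  }
  mu
}

#' Simulate the constant biological background
#'
#' Background miRNAs share one relative-abundance profile across all samples
#' (nominal fold-change 0 for every pair); only depth, the optional bias
#' scenarios and count noise differ between samples.
#'
#' @param cfg A [sim_config()].
#' @param n_samples Number of samples (default 12).
#' @return A `count_matrix` of background counts.
#' @export
simulate_background <- function(cfg, n_samples = 12) {
  with_seed(cfg$seed, {
    ids <- sprintf("S%02d", seq_len(n_samples))
    mu <- background_means(cfg, n_samples, ids)
    counts <- matrix(nb_draw(mu, cfg$dispersion), nrow(mu), ncol(mu),
                     dimnames = dimnames(mu))
    count_matrix(counts)
  })
}

#' Simulate spike-in counts under a dilution design
#'
#' Expected count of spike-in s in sample i is
#' `kappa_s * amount[i, s] * depth_i / mean(depth)`: proportional to the
#' spiked amount, scaled with sequencing depth. Capture efficiencies kappa_s
#' are drawn log-normally once per spike-in and shared across samples, so the
#' true log-log dilution slope is exactly 1 and any estimated deviation
#' measures pipeline bias. A 0-amol well yields a count of exactly 0.
#'
#' @param design A [make_latin_square_design()].
#' @param cfg A [sim_config()].
#' @return A `count_matrix` of spike-in counts (`is_spikein` all `TRUE`),
#'   spike-ins in rows and samples in columns.
#' @export
simulate_spikein_counts <- function(design, cfg) {
  with_seed(cfg$seed + 1L, {
    n <- design$n
    ids <- rownames(design$assignment)
    depths <- resolve_depths(cfg, n)
    kappa <- stats::rlnorm(n, log(cfg$kappa_per_amol), cfg$kappa_sdlog)
    mu <- t(design$assignment) * kappa # spike-ins x samples
    mu <- sweep(mu, 2, depths / mean(depths), `*`)
    counts <- matrix(nb_draw(mu, cfg$dispersion), nrow(mu), ncol(mu),
                     dimnames = list(colnames(design$assignment), ids))
    count_matrix(counts, is_spikein = rep(TRUE, n))
  })
}

#' Simulate a full spike-in benchmark dataset
#'
#' Stacks the simulated background and the spike-in dilution rows and emits
#' the ground truth: background features have nominal log2 fold-change 0 for
#' every sample pair; a spike-in's nominal fold-change between two samples is
#' the log2 ratio of its designed amounts, flagged infinite when one amount
#' is 0.
#'
#' @param cfg A [sim_config()].
#' @param design A `spikein_design`; default the 12x12 cyclic square.
#' @return Class `sim_dataset`: list with `counts` (a `count_matrix`),
#'   `design`, `truth` (long data frame of spike-in nominal log2 FCs for all
#'   ordered pairs; background truth is identically 0) and `config`.
#' @export
simulate_dataset <- function(cfg = sim_config(), design = make_latin_square_design()) {
  bg <- simulate_background(cfg, n_samples = design$n)
  sp <- simulate_spikein_counts(design, cfg)
  stopifnot(identical(samples(bg), samples(sp)))
  counts <- count_matrix(rbind(bg$counts, sp$counts),
                         c(bg$is_spikein, sp$is_spikein))
  structure(list(counts = counts, design = design,
                 truth = spikein_truth(design), config = cfg),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("sim_dataset: %d features (%d spike-ins) x %d samples, seed %d\n",
              nrow(x$counts$counts), sum(x$counts$is_spikein),
              ncol(x$counts$counts), x$config$seed))
  invisible(x)
}

#' Nominal spike-in fold-changes for all sample pairs
#'
#' @param design A `spikein_design`.
#' @return Data frame with columns `feature`, `sample_a`, `sample_b`,
#'   `nominal_log2fc` (log2 of the amount ratio a/b; `NA` when flagged) and
#'   `infinite` (`TRUE` when exactly one amount is 0 — a positive,
#'   infinite-fold change; pairs where both amounts are 0 cannot occur in a
#'   Latin Square of distinct concentrations).
#' @export
spikein_truth <- function(design) {
  a <- design$assignment
  sids <- rownames(a)
  pairs <- utils::combn(sids, 2)
  do.call(rbind, lapply(seq_len(ncol(pairs)), function(p) {
    i <- pairs[1, p]; j <- pairs[2, p]
    inf <- xor(a[i, ] == 0, a[j, ] == 0)
    data.frame(feature = colnames(a), sample_a = i, sample_b = j,
               nominal_log2fc = ifelse(inf, NA, log2(a[i, ] / a[j, ])),
               infinite = inf, row.names = NULL)
  }))
}

#' Ground truth for one sample pair over all features
#'
#' @param ds A `sim_dataset`.
#' @param sample_a,sample_b Sample ids; fold-changes are oriented a over b.
#' @return Data frame with one row per feature of the dataset: columns
#'   `feature`, `is_spikein`, `nominal_log2fc` (0 for background) and
#'   `infinite`.
#' @export
pair_truth <- function(ds, sample_a, sample_b) {
  feat <- features(ds$counts)
  out <- data.frame(feature = feat, is_spikein = ds$counts$is_spikein,
                    nominal_log2fc = 0, infinite = FALSE)
  tr <- ds$truth
  sel <- (tr$sample_a == sample_a & tr$sample_b == sample_b)
  rev <- (tr$sample_a == sample_b & tr$sample_b == sample_a)
  if (!any(sel) && !any(rev)) stop("unknown sample pair")
  tr <- if (any(sel)) tr[sel, ] else transform(tr[rev, ], nominal_log2fc = -nominal_log2fc)
  idx <- match(tr$feature, out$feature)
  out$nominal_log2fc[idx] <- tr$nominal_log2fc
  out$infinite[idx] <- tr$infinite
  out
}
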