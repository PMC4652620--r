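---
title: "Benchmarking miRNA-seq normalization with spike-in dilution series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking miRNA-seq normalization with spike-in dilution series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikenorm)
```

## The evaluation model

A spike-in dilution experiment separates technical variation from biology by
construction. Twelve synthetic miRNA oligos — sequences absent from the human
genome — are added to aliquots of one common reference RNA at twelve known
amounts spanning 0 to 3276.8 attomoles, arranged as a cyclic Latin Square:
sample *i* receives spike-in *j* at `concentrations[(i + j) mod 12]`, so each
amount appears exactly once per sample and once per spike-in, and the total
spiked mass is identical in every sample. Every background miRNA therefore
has a true between-sample fold-change of 1, while every spike-in changes by
an exactly known ratio (the smallest nonzero ratio in the series is 2).

A normalization method is then judged by four questions:

1. **Variance.** Does it shrink the per-feature variance of log2(x+1) across
   samples for the (truly constant) background? Reported as the fraction of
   background features whose variance is *strictly* lower than in the raw
   counts, plus a variance-ratio-versus-abundance trend with a lowess
   smoother.
2. **Bias of the dilution response.** For each spike-in, ordinary least
   squares of `log2(count + 1)` on `log2(amount)` over the eleven nonzero
   amounts (the 0-amol well has no defined log amount). Slope 1 means
   normalized counts track the spiked amounts; R² measures series quality.
   Corrupted series can be excluded by id, mirroring how a pipetting-damaged
   series would be dropped in practice.
3. **Bias of fold-change estimates.** `log2((x_a+1)/(x_b+1))` for all 66
   sample pairs minus the nominal log ratios; the median should sit at 0.
   Pairs against a 0-amol well have no finite nominal value and are excluded
   here, but they count as positives in the precision–recall analysis.
4. **Detection accuracy.** Precision–recall curves sweeping the absolute
   estimated fold-change over all observed values: positives are spike-ins
   with nominal fold-change ≥ 2 (or infinite, i.e. versus a 0-amol well),
   negatives are the background. PR curves rather than ROC because the class
   imbalance is severe (12 spike-ins vs hundreds of background features).

## The normalization methods

Four scaling methods (counts-per-million; total-count scaling to the
median-size library; upper-quartile scaling anchored to the geometric mean of
per-sample 75th percentiles of expressed features; TMM), the median-of-ratios
size factor, and three distribution/regression methods (MA-plot linear
regression toward the per-feature median profile, cyclic loess, quantile
normalization). All are implemented in this package against their published
definitions, so every intermediate (trim sets, weights, smoother corrections)
is inspectable; on their shared domains the median-of-ratios factors agree
with `DESeq2::estimateSizeFactorsForMatrix` to 1e-10 and quantile
normalization agrees with `limma::normalizeQuantiles` on tie-free data (the
packages differ in tie handling — we average the reference values across a
tie block, which keeps the result invariant under permutation of tied
entries).

Choices the method definitions leave open, and what this package does:

* **TMM details.** Trim 30% of M (15% per tail) and 5% of A (2.5% per tail)
  by linear-interpolation quantiles, keep the intersection, weight by the
  inverse delta-method variance `(s_k−x_k)/(s_k x_k) + (s_r−x_r)/(s_r x_r)`,
  and rescale factors to geometric mean 1. The reference sample (when not
  given) is the one whose 75th percentile of depth-scaled counts is closest
  to the mean such percentile. Normalized counts are
  `x · Ñ / (s_k f_k)` with `Ñ` the geometric-mean library size, so output
  stays on a count-like scale.
* **Upper-quartile anchor.** Factors `g/q_i` with `g` the geometric mean of
  the quartiles — symmetric in the samples and order-independent, rather than
  anchored to one arbitrary reference sample.
* **Linear regression / loess baseline.** The regression methods need a
  baseline channel. We use the per-feature median across samples as a fixed
  synthetic baseline and adjust only the sample under correction; adjusting
  both channels would move the baseline between samples. Cyclic loess
  instead works on all unordered sample pairs on the log2(x+1) scale, span
  0.7 and 3 cycles by default (the algorithm's customary operating range;
  both exposed as arguments), splitting each correction evenly between the
  pair. Pairs sharing fewer than 10 positive features are skipped with a
  warning.
* **Quantile ties.** All members of a tie block receive the mean of the
  reference values at the tied ranks. On tied data this deliberately breaks
  the "all sorted columns identical" idealization — tie-block means differ
  from the individual reference values — which is the standard trade-off.
* **Baseline sample.** The median library size; with an even number of
  samples the lower of the two middle values, ties broken by sample id, so
  the baseline is always a real sample and the choice is order-independent.
* **Pseudocounts.** All log transforms add +1 (zero safety). The dilution
  regression exposes `pseudocount`; with the default +1 the bottom of a
  weakly captured series is flattened and slopes attenuate slightly
  (about 0.02 under the generator's defaults), while `pseudocount = 0`
  reproduces the plain log-log model exactly on positive series.
* **Precision at zero calls** is defined as 1; thresholds sweep every
  observed unique |log2 FC| plus +∞; the area is the step integral of
  precision over recall. Note that the null (random-ranking) expectation of
  this area exceeds the prevalence P/N in small samples — exactly
  `(1/P) Σᵢ E[i/posᵢ]` with `posᵢ` negative-hypergeometric — which the test
  suite uses as its reference value.

## What the generator simulates

`sim_config()` defaults define the reference condition:

| parameter | default | meaning |
|---|---|---|
| `n_background` | 500 | background miRNAs, shares drawn log-normal(sd 1.5) |
| `depths` | 2e5 | expected background reads per sample |
| `dispersion` | 0.05 | negative-binomial dispersion (0 = Poisson) |
| `kappa_per_amol` | 30 | expected spike-in counts per amol at reference depth |
| `kappa_sdlog` | 0.5 | spread of per-spike-in capture efficiencies |

Counts are negative binomial around expected values; a spike-in's expectation
is `κ_s · amount · depth_i / mean(depth)` with one capture efficiency `κ_s`
per spike-in shared across samples, so the generator's true dilution slope is
exactly 1 and any estimated deviation measures pipeline-induced bias. A
0-amol well yields exactly zero counts. `kappa_per_amol = 30` puts the lowest
nonzero dilution (0.1 amol) at ~3 expected counts — detectable but noisy,
like the bottom of a real dilution series — while keeping the +1 pseudocount
negligible for the rest of the series; with far smaller capture efficiencies
the pseudocount itself would flatten the series bottom and attenuate slopes
regardless of normalization. Depths are desk-scale (10⁵–5×10⁵ reads when
variable) rather than the millions of a production run; every conclusion the
package draws is scale-free, and depth is configurable.

Two named scenarios (`scenario_config()`) fix the study conditions used by
the analysis scripts, the acceptance script and the end-to-end tests:

* **reference** — equal expected depths, no distortions. All scaling methods
  should be near no-ops here; used for parameter recovery (median dilution
  slope within [0.9, 1.1] across seeds).
* **variable_depth_composition** — depths drawn uniformly from 1e5–5e5 and a
  composition-bias scenario: the 2% most abundant background features are
  8-fold up in half the samples. Composition bias is by definition the
  distortion caused by a small minority of highly expressed features
  consuming sequencing real estate, so the scenario targets the most
  abundant features; those features keep nominal truth 0 (they model
  unannotated asymmetric expression contaminating the null), which is
  precisely what defeats library-size-based scaling while the trimmed and
  median-based estimators ignore it. An `intensity_distortion` scenario
  (a smooth 2^g(A) warp) is also available to exercise the loess method.

What the generator does **not** emulate: alignment and multi-mapping
artifacts, isomiR collapsing, sequence-specific ligation bias (capture
efficiency is one number per spike-in, not a sequence model), adapter
chemistry, or the unknown true dispersion and abundance spectrum of the real
reference RNA. Passing the end-to-end tests therefore shows the *procedure*
behaves correctly under known, controlled violations of the scaling
assumptions — not that any particular method is optimal for a given real
library preparation.

## Numerical and degenerate-input policy

* Matrices are features × rows, samples × columns; all per-sample statistics
  are column statistics. Zero-sum columns are errors for scaling methods.
* Percentiles use linear interpolation between order statistics throughout.
* TMM with an empty post-trim survivor set falls back to factor 1 with a
  warning; a single shared-positive feature determines the factor alone.
* Degenerate dilution series (all counts equal) report slope 0, R² 0 and a
  `degenerate` flag rather than failing the whole fit table.
* `downsample()` refuses fractional (already-normalized) matrices and draws
  exact multivariate hypergeometric column subsamples, so column sums hit the
  target depth exactly and no cell exceeds its original count.
* Variance-ratio trends exclude features with zero raw variance or a
  non-finite log ratio; with fewer than 10 usable features the smoother is
  omitted.

## Problem sizes

The shipped analysis, tests and acceptance script run the 12-sample design
with 500 background features, five seeds per stochastic claim, and all
normalization methods; a full benchmark of one dataset takes a few seconds on
one CPU, and the complete test suite stays within a couple of minutes.
Stochastic assertions (slope recovery, method rankings) use majority votes
across the five seeds at the tolerances stated in the test names, and every
simulated quantity flows from a single integer seed.

## Limitations

The comparison inherits the spike-in design's blind spots: truth exists only
for 12 features per dataset, background "constancy" is an assumption about
the shared reference rather than a measured fact, and fold-change truth for
pairs involving a 0-amol well is categorical (infinite) rather than numeric.
The qualitative method ranking under composition bias is a property of the
simulated mechanism; on real data the size of the effect depends on how much
asymmetric high-abundance expression the libraries actually contain.
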