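# spikenorm

Benchmarking count-normalization methods for miRNA sequencing against a
spike-in dilution ground truth.

## The problem

Small RNA-seq yields a count matrix of miRNAs (rows) by samples (columns).
Before any comparison between samples, the counts must be normalized for
sequencing depth and composition, and the choice of method changes what a
downstream differential-expression analysis reports. The clean way to compare
normalization methods is an experiment where truth is known: synthetic
*A. thaliana* miRNA oligos spiked into a constant human background at twelve
known amounts (0, 0.1, 0.2, 0.8, 1.6, 6.4, 12.8, 51.2, 102.4, 409.6, 819.2,
3276.8 amol) arranged as a 12 × 12 cyclic Latin Square, so each amount occurs
exactly once per sample and once per spike-in. Background miRNAs should not
change between samples; spike-ins change by known ratios.

`spikenorm` implements that comparison procedure end to end:

* **Eight normalization methods.** With library size `s_i` and baseline
  `s_baseline` (the median-size sample):

  * counts-per-million: `x' = x · 10⁶ / s_i`
  * total-count scaling: `d_i = s_baseline / s_i`, `x' = d_i · x`
  * upper-quartile scaling: factors `g / q_i` from the per-sample 75th
    percentile of expressed features, `g` the geometric mean of the `q_i`
  * trimmed mean of M-values (TMM): precision-weighted mean of per-feature
    log-ratios `M` against a reference after trimming 30% of `M` and 5% of
    the average intensity `A`
  * median-of-ratios size factors: `sf_j = median_i( x_ij / (∏_k x_ik)^{1/n} )`
    over features with no zeros
  * linear-regression MA correction: per sample, OLS fit `M = β₀ + β₁A`
    against the median baseline profile, fitted trend subtracted
  * cyclic loess: pairwise lowess smoother `c(A)` of `M` on `A`, half the
    correction applied to each sample, cycled
  * quantile normalization with block-mean tie handling

* **A synthetic-data generator** emulating the spike-in experiment: cyclic
  Latin-Square design, log-normal background abundances, negative-binomial
  counts, per-spike-in capture efficiencies (so the true dilution slope
  is exactly 1), plus optional variable depths, composition bias and
  intensity-dependent distortion.

* **The benchmarking metrics**: relative log expression (RLE), per-feature
  variance change (`% with lower variance`), the dilution-series bias model
  `log₂C = β₀ + β₁·log₂a` fitted per spike-in over the nonzero amounts
  (slope 1 = unbiased), absolute fold-change bias against nominal ratios,
  precision–recall curves for calling the spike-ins differential (truth:
  fold-change ≥ 2), and Spearman fold-change concordance with
  complete-linkage clustering.

## Worked example

```r
library(spikenorm)

ds <- simulate_dataset(scenario_config("variable_depth_composition", seed = 1))
ds
#> sim_dataset: 512 features (12 spike-ins) x 12 samples, seed 1

bench <- run_benchmark(ds, methods = c("none", "cpm", "total_count",
                                       "upper_quartile", "tmm", "median_ratio"))
print(bench$summary, row.names = FALSE, digits = 4)
#>          method fraction_lower_variance median_beta1 median_r_squared pr_auc median_abs_bias
#>            none                  0.0000       0.9674           0.9859 0.8283      -0.1316415
#>             cpm                  0.1167       0.9744           0.9802 0.8286       0.7254609
#>     total_count                  0.1247       0.9639           0.9810 0.8257       0.7203697
#>  upper_quartile                  0.9618       0.9690           0.9929 0.8617      -0.0168016
#>             tmm                  0.9698       0.9706           0.9926 0.8642      -0.0032640
#>    median_ratio                  0.9759       0.9705           0.9926 0.8642      -0.0006992
```

Reading the row for `tmm`: after TMM normalization 97% of background miRNAs
have lower variance than in the raw counts, the median dilution-series slope
is 0.97 (≈ 1 means counts track the spiked amounts), the pooled
precision–recall area over all 66 sample pairs is 0.86, and the median
absolute bias of fold-change estimates is ~0.003 log2 units. Compare
`total_count`: variance is reduced for only 12% of the background and
fold-changes are off by a median 0.72 log2 units — the composition bias and
depth differences corrupt total-count scaling while the robust scalings
(TMM, upper-quartile, median-of-ratios) absorb them.

The full workflow (simulate → benchmark → report) lives in `analysis/`:

```sh
Rscript analysis/01_simulate.R --seed 1   # writes results/data/
Rscript analysis/02_benchmark.R --seed 1  # writes results/benchmark/
Rscript analysis/03_report.R              # prints the findings
```

## Package layout

* `R/count_matrix.R` — count container, TSV I/O, low-count filter
  (≥ 5 counts in ≥ 25% of samples), log2(x+1), library sizes, exact
  hypergeometric downsampling
* `R/normalize.R` — the eight normalization methods plus dispatch
* `R/simulate.R` — Latin-Square design and the spike-in experiment generator
* `R/evaluate.R` — RLE, variance, bias, fold-change and precision–recall metrics
* `R/benchmark.R` — the end-to-end benchmark and TSV writers
* `vignettes/spikein-benchmarking.Rmd` — methods, assumptions, design choices
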