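#!/usr/bin/env Rscript
# Generate the two study datasets: a reference spike-in experiment (equal
# depths, no distortions) and a stress scenario with variable sequencing
# depth plus composition bias. Each is a 12x12 cyclic Latin-Square dilution
# design over a 500-miRNA constant background.

suppressPackageStartupMessages(library(spikenorm))

seed <- 1L
args <- commandArgs(trailingOnly = TRUE)
if (length(args) >= 2 && args[1] == "--seed") seed <- as.integer(args[2])

for (scen in c("reference", "variable_depth_composition")) {
  dir <- file.path("results", "data", scen)
  ds <- simulate_to_files(scenario_config(scen, seed = seed), dir)
  sizes <- colSums(ds$counts$counts)
  message(sprintf("%s: %d features x %d samples; library sizes %s-%s reads",
                  scen, nrow(ds$counts$counts), ncol(ds$counts$counts),
                  format(round(min(sizes))), format(round(max(sizes)))))
}
message("wrote counts/truth/design/config bundles under results/data/")
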