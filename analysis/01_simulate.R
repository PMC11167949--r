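#!/usr/bin/env Rscript
# Step 1: simulate the two-population cohort with known truth.
# Emits VCF + FASTA + GFF3 + truth/population tables into scratch/cohort
# and a small truth-composition table into results/.

source("analysis/00_config.R")

cfg <- cohort_config()
sim <- simulate_cohort(cfg, COHORT_DIR)

comp <- as.data.frame(table(category = sim$truth$planted_category),
                      stringsAsFactors = FALSE)
names(comp)[2] <- "n_sites"
write_tsv(comp, "01_truth_composition.tsv")

message(sprintf(
  "simulated %d sites x %d samples; planted %d divergent sites; sweep region %s:%d-%d",
  nrow(sim$cohort$sites), length(sim$cohort$samples),
  sum(sim$truth$planted_category != "NEUTRAL"),
  cfg$sweep_region$chrom, cfg$sweep_region$start, cfg$sweep_region$end
))
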