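#!/usr/bin/env Rscript
# Step 5: sliding-window Weir-Cockerham FST and nucleotide diversity,
# joint top-5% window selection, candidate BED and putatively selected
# genes (PSGs).

source("analysis/00_config.R")

co <- read_vcf(file.path(COHORT_DIR, "cohort.filtered.vcf"))
pops <- read_populations(file.path(COHORT_DIR, "populations.tsv"),
                         co$samples)
models <- gene_models(file.path(COHORT_DIR, "genes.gff3"))
cfg <- cohort_config()

ws <- window_stats(co, pops, cfg$chrom_lengths, "POPA", "POPB")
sel <- select_top_windows(ws)
utils::write.table(sel, file.path(COHORT_DIR, "windows.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
thr <- data.frame(statistic = c("fst", "pi_ratio"),
                  top5_threshold = c(attr(sel, "fst_threshold"),
                                     attr(sel, "ratio_threshold")))
write_tsv(thr, "05_top5_thresholds.tsv")

cand <- sel[sel$candidate, , drop = FALSE]
bed <- data.frame(chrom = cand$chrom, start = cand$start, end = cand$end)
utils::write.table(bed, file.path(RESULTS_DIR, "05_candidate_windows.bed"),
                   sep = "\t", quote = FALSE, row.names = FALSE,
                   col.names = FALSE)

psg <- windows_to_genes(sel, models$genes)
write_tsv(data.frame(gene_id = psg), "05_psg_genes.tsv")

region <- cfg$sweep_region
n_hit <- sum(cand$chrom == region$chrom & cand$start < region$end &
               cand$end > region$start)
message(sprintf(
  "windows: %d; FST threshold %.3f, pi-ratio threshold %.3f; %d candidates (%d overlap the planted sweep); %d PSGs",
  nrow(sel), attr(sel, "fst_threshold"), attr(sel, "ratio_threshold"),
  nrow(cand), n_hit, length(psg)
))
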