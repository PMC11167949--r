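# Shared settings for the analysis drivers. Simulated raw data (VCF,
# FASTA, GFF3) land in scratch/; small result tables land in results/.

suppressMessages(library(dafscreen))

ANALYSIS_SEED <- 20260920L
COHORT_DIR <- "scratch/cohort"
RESULTS_DIR <- "results"
dir.create(COHORT_DIR, showWarnings = FALSE, recursive = TRUE)
dir.create(RESULTS_DIR, showWarnings = FALSE, recursive = TRUE)

# study-scale synthetic cohort: two 5 Mb chromosomes, ~20k SNPs,
# 44 + 29 diploids, one sweep footprint on chr2
cohort_config <- function(seed = ANALYSIS_SEED) {
  sim_config(
    n_sites = 20000L,
    chrom_lengths = c(chr1 = 5e6, chr2 = 5e6),
    sweep_region = list(chrom = "chr2", start = 2000001L, end = 2300000L,
                        target = "a", diversity_factor = 0.1),
    n_genes = 60L,
    seed = seed
  )
}

write_tsv <- function(df, name) {
  path <- file.path(RESULTS_DIR, name)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", path)
  invisible(path)
}
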