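#!/usr/bin/env Rscript
# Step 6: summary surfaces. Category percentages for the synthetic
# cohort, the same arithmetic applied to the published screen counts,
# per-chromosome shares, and candidate/PSG/curated-list overlaps.

source("analysis/00_config.R")

cl <- utils::read.delim(file.path(COHORT_DIR, "classified_snps.tsv"))
filter_rep <- utils::read.delim(file.path(RESULTS_DIR,
                                          "02_filter_report.tsv"))
total <- filter_rep$n_pass[1]

counts <- c(
  a_specific = sum(cl$category == "A_SPECIFIC"),
  a_predominant = sum(cl$category == "A_PREDOMINANT"),
  b_specific = sum(cl$category == "B_SPECIFIC"),
  b_predominant = sum(cl$category == "B_PREDOMINANT")
)
write_tsv(category_summary(counts, total), "06_category_summary.tsv")
write_tsv(per_chromosome_summary(cl), "06_per_chromosome.tsv")

# the same reporting arithmetic on the published counts of the
# TIB (Tibetan) vs LW (Large White) screen: 21,767,938 post-filter SNPs
published <- category_summary(
  c(a_specific = 1114731, a_predominant = 1778375,
    b_specific = 53491, b_predominant = 759819),
  21767938
)
write_tsv(published, "06_published_scale_summary.tsv")

cand_genes <- utils::read.delim(file.path(RESULTS_DIR,
                                          "04_candidate_genes.tsv"))$gene_id
psg <- utils::read.delim(file.path(RESULTS_DIR, "05_psg_genes.tsv"))$gene_id
# stand-in curated list (synthetic): half the PSGs plus unrelated ids,
# emulating an externally curated trait-gene list
set.seed(ANALYSIS_SEED)
curated <- c(sample(psg, ceiling(length(psg) / 2)),
             sprintf("trait_gene%02d", 1:5))
ov <- overlap_report(list(candidate = cand_genes, psg = psg,
                          curated = curated))
write_tsv(ov$regions, "06_gene_set_overlaps.tsv")

message(sprintf(
  "synthetic screen: %d/%d (%.2f%%) combined divergent calls; PSG/curated overlap %d",
  counts[["a_specific"]] + counts[["a_predominant"]] +
    counts[["b_specific"]] + counts[["b_predominant"]],
  total,
  100 * (counts[["a_specific"]] + counts[["a_predominant"]] +
           counts[["b_specific"]] + counts[["b_predominant"]]) / total,
  ov$regions$n_intersection[ov$regions$combo == "psg&curated"]
))
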