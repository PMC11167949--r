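#!/usr/bin/env Rscript
# Step 4: assign classified SNPs to gene models (gene body +/- 1 kb) and
# functional effect classes; aggregate per-gene candidate counts.

source("analysis/00_config.R")

co <- read_vcf(file.path(COHORT_DIR, "cohort.filtered.vcf"))
models <- gene_models(file.path(COHORT_DIR, "genes.gff3"))
genome <- load_genome(file.path(COHORT_DIR, "genome.fa"))
cl <- utils::read.delim(file.path(COHORT_DIR, "classified_snps.tsv"))

ann <- annotate_sites(co$sites, models, genome)
utils::write.table(ann, file.path(COHORT_DIR, "annotation.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

eff <- as.data.frame(table(effect = ann$effect), stringsAsFactors = FALSE)
names(eff)[2] <- "n_snps"
write_tsv(eff, "04_effect_classes.tsv")

agg <- aggregate_candidate_genes(cl, ann)
write_tsv(agg$by_category, "04_genes_by_category.tsv")
write_tsv(agg$by_effect, "04_genes_by_effect.tsv")
write_tsv(data.frame(gene_id = agg$candidate_genes), "04_candidate_genes.tsv")

message(sprintf("annotated %d sites over %d gene models; %d candidate genes carry classified SNPs",
                nrow(ann), nrow(models$genes), length(agg$candidate_genes)))
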