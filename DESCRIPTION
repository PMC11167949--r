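Package: dafscreen
Title: Allele-Frequency Divergence Screening and Selective-Sweep Scanning
    for Two-Population Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens biallelic SNPs for breed-specific and breed-predominant
    alleles between two populations using per-population allele frequencies
    and their absolute difference, applies GATK-style site-level hard
    filters (quality-by-depth, mapping quality, strand bias, rank sums,
    SNP clusters, biallelicity, missingness), annotates variants to gene
    models with a 1 kb upstream/downstream window and coding-effect calls,
    and scans the genome for selective sweeps with weighted Weir-Cockerham
    FST and nucleotide-diversity ratios in 50 kb sliding windows. Includes
    a two-population diploid cohort simulator that emits VCF, FASTA, GFF3
    and truth tables with planted divergent sites and sweep regions for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    vcfR,
    ape,
    Biostrings,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
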