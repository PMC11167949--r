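# In-code fixture builders shared across test files.

# minimal cohort from explicit dosage rows: geno is a matrix with one row
# per site (samples in columns), NA = missing
make_cohort <- function(pos, geno, chrom = "chr1", ref = "A", alt = "G",
                        qual = 100, qd = 25, mq = 60, fs = 1,
                        mqranksum = 0, readposranksum = 0) {
  n <- length(pos)
  geno <- matrix(as.integer(geno), nrow = n)
  colnames(geno) <- sprintf("S%02d", seq_len(ncol(geno)))
  structure(list(
    sites = data.frame(
      chrom = rep_len(chrom, n), pos = as.integer(pos), id = ".",
      ref = rep_len(ref, n), alt = rep_len(alt, n),
      qual = rep_len(qual, n), qd = rep_len(qd, n), mq = rep_len(mq, n),
      fs = rep_len(fs, n), mqranksum = rep_len(mqranksum, n),
      readposranksum = rep_len(readposranksum, n),
      stringsAsFactors = FALSE
    ),
    geno = geno,
    samples = colnames(geno)
  ), class = "dafscreen_cohort")
}

# random two-population dosage matrix with independent per-pop frequencies
random_two_pop_geno <- function(n_sites, n_a, n_b, miss = 0.05) {
  p <- stats::runif(n_sites, 0.05, 0.95)
  q <- stats::runif(n_sites, 0.05, 0.95)
  ga <- matrix(stats::rbinom(n_sites * n_a, 2, rep(p, n_a)), nrow = n_sites)
  gb <- matrix(stats::rbinom(n_sites * n_b, 2, rep(q, n_b)), nrow = n_sites)
  g <- cbind(ga, gb)
  g[stats::runif(length(g)) < miss] <- NA_integer_
  g
}

two_pop_table <- function(n_a, n_b) {
  data.frame(
    sample = c(sprintf("S%02d", seq_len(n_a + n_b))),
    population = rep(c("POPA", "POPB"), c(n_a, n_b))
  )
}

# hand-built two-gene annotation fixture: a plus-strand and a minus-strand
# gene with known codon layout, plus an overlapping-gene pair
annotation_fixture <- function(dir) {
  len <- 10000L
  genome <- rep("A", len)
  # plus-strand gene: exon1 2001-2100 (UTR5 2001-2030, CDS 2031-2100),
  # intron 2101-2300, exon2 2301-2430 (CDS 2301-2400, UTR3 2401-2430)
  # CDS length 170... make divisible by 3: 70 + 100 = 170 -> adjust to
  # CDS1 2031-2100 (70) and CDS2 2301-2403 (103)?  Use 70 + 104 = 174.
  cds1 <- 2031:2100                       # 70 bases
  cds2 <- 2301:2404                       # 104 bases -> total 174 = 58 codons
  coding <- paste0("ATG",
                   strrep("GCT", 56),     # alanines
                   "TAA")
  stopifnot(nchar(coding) == length(cds1) + length(cds2))
  genome[c(cds1, cds2)] <- strsplit(coding, "")[[1]]
  # minus-strand gene at 6001-6600: single exon, CDS 6051-6550 reverse
  # complement of ATG + 164 GCT? 500 bases: 3 + 495 + ... use CDS len 501
  cds3 <- 6051:6551                       # 501 bases = 167 codons
  coding2 <- paste0("ATG", strrep("GAT", 165), "TAA")
  stopifnot(nchar(coding2) == length(cds3))
  rc <- rev(unname(c(A = "T", C = "G", G = "C", T = "A")[strsplit(coding2, "")[[1]]]))
  genome[cds3] <- rc
  # overlapping pair around 8000
  gff <- c(
    "##gff-version 3",
    "chr1\ttest\tgene\t2001\t2430\t.\t+\t.\tID=geneP",
    "chr1\ttest\tmRNA\t2001\t2430\t.\t+\t.\tID=txP;Parent=geneP",
    "chr1\ttest\texon\t2001\t2100\t.\t+\t.\tID=txP.e1;Parent=txP",
    "chr1\ttest\texon\t2301\t2430\t.\t+\t.\tID=txP.e2;Parent=txP",
    "chr1\ttest\tCDS\t2031\t2100\t.\t+\t0\tID=txP.c1;Parent=txP",
    "chr1\ttest\tCDS\t2301\t2404\t.\t+\t0\tID=txP.c2;Parent=txP",
    "chr1\ttest\tgene\t6001\t6600\t.\t-\t.\tID=geneM",
    "chr1\ttest\tmRNA\t6001\t6600\t.\t-\t.\tID=txM;Parent=geneM",
    "chr1\ttest\texon\t6001\t6600\t.\t-\t.\tID=txM.e1;Parent=txM",
    "chr1\ttest\tCDS\t6051\t6551\t.\t-\t0\tID=txM.c1;Parent=txM",
    "chr1\ttest\tgene\t7900\t8200\t.\t+\t.\tID=geneO1",
    "chr1\ttest\tmRNA\t7900\t8200\t.\t+\t.\tID=txO1;Parent=geneO1",
    "chr1\ttest\texon\t7900\t8200\t.\t+\t.\tID=txO1.e1;Parent=txO1",
    "chr1\ttest\tgene\t8100\t8400\t.\t+\t.\tID=geneO2",
    "chr1\ttest\tmRNA\t8100\t8400\t.\t+\t.\tID=txO2;Parent=geneO2",
    "chr1\ttest\texon\t8100\t8400\t.\t+\t.\tID=txO2.e1;Parent=txO2"
  )
  gff_path <- file.path(dir, "fixture.gff3")
  fa_path <- file.path(dir, "fixture.fa")
  writeLines(gff, gff_path)
  writeLines(c(">chr1", paste(genome, collapse = "")), fa_path)
  list(gff = gff_path, fasta = fa_path, genome = genome,
       cds1 = cds1, cds2 = cds2, cds3 = cds3)
}
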