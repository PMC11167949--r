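# Independent brute-force reference implementations used to validate the
# package's estimators. These are deliberately written in the plainest
# scalar style, from the defining formulas, and share no code with R/.

# literal transcription of the screening rules for a single allele
oracle_classify <- function(af_focal, af_other, threshold = 0.5) {
  if (is.na(af_focal) || is.na(af_other)) return("NONE")
  if (af_focal < threshold) return("NONE")
  if (af_other >= threshold) return("NONE")
  if (af_other == 0) return("SPECIFIC")
  if (abs(af_focal - af_other) >= threshold) return("PREDOMINANT")
  "NONE"
}

# bisection root of the population-mean curve a(2p - 1) + 2p(1 - p)d
oracle_threshold_p <- function(d_over_a, tol = 1e-12) {
  f <- function(p) (2 * p - 1) + 2 * p * (1 - p) * d_over_a
  lo <- 0; hi <- 1
  stopifnot(f(lo) < 0, f(hi) > 0)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Weir & Cockerham (1984) per-site components for r populations, written
# as an explicit loop over populations; geno_list holds one dosage vector
# (0/1/2, NA missing) per population
oracle_wc_components <- function(geno_list) {
  r <- length(geno_list)
  n <- p <- h <- numeric(r)
  for (i in seq_len(r)) {
    g <- geno_list[[i]][!is.na(geno_list[[i]])]
    n[i] <- length(g)
    p[i] <- sum(g) / (2 * length(g))
    h[i] <- mean(g == 1)
  }
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - 1 / (nbar - 1) *
       (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 -
       (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

# weighted window FST from scratch
oracle_window_fst <- function(genoA, genoB) {
  num <- 0; den <- 0
  for (i in seq_len(nrow(genoA))) {
    ga <- genoA[i, ]; gb <- genoB[i, ]
    if (all(is.na(ga)) || all(is.na(gb))) next
    comp <- oracle_wc_components(list(ga, gb))
    num <- num + comp["a"]
    den <- den + sum(comp)
  }
  unname(num / den)
}

# per-bp pi by explicit pairwise allele comparison
oracle_window_pi <- function(geno, window_len) {
  total <- 0
  for (i in seq_len(nrow(geno))) {
    g <- geno[i, ][!is.na(geno[i, ])]
    alleles <- unlist(lapply(g, function(d) c(rep(1, d), rep(0, 2 - d))))
    n <- length(alleles)
    if (n < 2) next
    diffs <- 0; pairs <- 0
    for (x in seq_len(n - 1)) {
      for (y in (x + 1):n) {
        pairs <- pairs + 1
        if (alleles[x] != alleles[y]) diffs <- diffs + 1
      }
    }
    total <- total + diffs / pairs
  }
  total / window_len
}

# enumerate every window of `window_bp` consecutive bases; flag all SNPs
# in any window holding >= cluster_size of them
oracle_cluster_flags <- function(pos, cluster_size = 2, window_bp = 5) {
  flagged <- logical(length(pos))
  for (s in (min(pos) - window_bp):(max(pos))) {
    inside <- which(pos >= s & pos <= s + window_bp - 1)
    if (length(inside) >= cluster_size) flagged[inside] <- TRUE
  }
  flagged
}

# independent effect classifier: paints the gene span base by base, and
# decides coding effects by translating the entire CDS with Biostrings
oracle_effect <- function(pos, ref, alt, gene, tx, chromseq, flank = 1000) {
  if (pos < gene$start - flank || pos > gene$end + flank) return("intergenic")
  if (pos < gene$start) {
    return(if (gene$strand == "+") "upstream" else "downstream")
  }
  if (pos > gene$end) {
    return(if (gene$strand == "+") "downstream" else "upstream")
  }
  ex <- tx$exons; cds <- tx$cds
  cds_pos <- unlist(Map(seq, cds$start, cds$end))
  exon_pos <- unlist(Map(seq, ex$start, ex$end))
  if (pos %in% cds_pos) {
    translate_cds <- function(seqchars) {
      bases <- seqchars[cds_pos]
      s <- paste(bases, collapse = "")
      dna <- Biostrings::DNAString(s)
      if (gene$strand == "-") dna <- Biostrings::reverseComplement(dna)
      as.character(Biostrings::translate(dna, no.init.codon = TRUE))
    }
    stopifnot(chromseq[pos] == ref)
    prot_ref <- translate_cds(chromseq)
    mutated <- chromseq
    mutated[pos] <- alt
    prot_alt <- translate_cds(mutated)
    if (identical(prot_ref, prot_alt)) return("synonymous")
    aa_ref <- strsplit(prot_ref, "")[[1]]
    aa_alt <- strsplit(prot_alt, "")[[1]]
    i <- which(aa_ref != aa_alt)[1]
    if (aa_alt[i] == "*" && aa_ref[i] != "*") return("stop_gained")
    return("missense")
  }
  if (pos %in% exon_pos) {
    # exonic: splice region when within 3 bp of an exon/intron junction
    for (e in seq_len(nrow(ex))) {
      if (pos >= ex$start[e] && pos <= ex$end[e]) {
        if (e > 1 && pos - ex$start[e] < 3) return("splice_region")
        if (e < nrow(ex) && ex$end[e] - pos < 3) return("splice_region")
      }
    }
    if (nrow(cds) == 0) return("intron")
    left_of_cds <- pos < min(cds$start)
    if (gene$strand == "+") {
      return(if (left_of_cds) "five_prime_utr" else "three_prime_utr")
    }
    return(if (left_of_cds) "three_prime_utr" else "five_prime_utr")
  }
  # intronic: distance 1-8 bp from the closest exon edge is splice region
  d <- min(abs(pos - c(ex$start, ex$end)))
  if (d <= 8) return("splice_region")
  "intron"
}
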