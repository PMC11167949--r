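#' Build a simulation configuration for a two-population cohort
#'
#' Defaults describe the study regime the package targets: 44 + 29
#' diploid samples, baseline allele frequencies shared between the
#' populations and drawn from a symmetric U-shaped Beta (folded-spectrum
#' stand-in), a small planted fraction of divergent sites per category,
#' per-genotype missingness below the 10% site filter, and optionally one
#' low-diversity/high-differentiation region for the sweep scan.
#'
#' @param n_pop_a,n_pop_b diploid sample counts (defaults 44 and 29).
#' @param n_sites total biallelic SNPs to emit.
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param af_beta shape parameters of the baseline Beta AF distribution.
#' @param frac_specific_a,frac_specific_b,frac_predominant_a,frac_predominant_b
#'   fractions of sites planted in each screening category.
#' @param missing_rate per-genotype missingness probability, in \[0, 0.10);
#'   per-site missing counts are capped at the filter bound so planted
#'   sites always survive the missingness filter.
#' @param sweep_region `NULL` or a list with `chrom`, `start`, `end` (bp,
#'   1-based inclusive), `target` (`"a"` or `"b"`), `diversity_factor`
#'   (fraction of expected heterozygosity retained in the target
#'   population, in (0, 1)).
#' @param n_genes synthetic protein-coding gene models to plant.
#' @param exact_af plant sample allele frequencies exactly (genotypes
#'   constructed, not sampled); forces deterministic category recovery.
#' @param seed integer RNG seed.
#' @return A `dafscreen_simconfig` list.
#' @export
sim_config <- function(n_pop_a = 44L, n_pop_b = 29L, n_sites = 2000L,
                       chrom_lengths = c(chr1 = 1e6, chr2 = 1e6),
                       af_beta = c(0.5, 0.5),
                       frac_specific_a = 0.05, frac_specific_b = 0.02,
                       frac_predominant_a = 0.05, frac_predominant_b = 0.02,
                       missing_rate = 0.05, sweep_region = NULL,
                       n_genes = 20L, exact_af = FALSE, seed = 1L) {
  fracs <- c(frac_specific_a, frac_specific_b,
             frac_predominant_a, frac_predominant_b)
  if (any(fracs < 0) || sum(fracs) > 1) {
    stop("category fractions must be >= 0 and sum to <= 1")
  }
  if (missing_rate < 0 || missing_rate >= 0.10) {
    stop("missing_rate must lie in [0, 0.10)")
  }
  if (is.null(names(chrom_lengths))) stop("chrom_lengths must be named")
  if (!is.null(sweep_region)) {
    if (!sweep_region$chrom %in% names(chrom_lengths)) {
      stop("sweep_region chromosome not simulated")
    }
    len <- chrom_lengths[[sweep_region$chrom]]
    if (sweep_region$start < 1 || sweep_region$end > len) {
      stop("sweep_region outside chromosome bounds")
    }
    if (len < 50000) stop("sweep chromosome shorter than one window")
    df <- sweep_region$diversity_factor
    if (is.null(df) || df <= 0 || df >= 1) {
      stop("diversity_factor must lie in (0, 1)")
    }
  }
  structure(list(
    n_pop_a = as.integer(n_pop_a), n_pop_b = as.integer(n_pop_b),
    n_sites = as.integer(n_sites), chrom_lengths = chrom_lengths,
    af_beta = af_beta,
    frac_specific_a = frac_specific_a, frac_specific_b = frac_specific_b,
    frac_predominant_a = frac_predominant_a,
    frac_predominant_b = frac_predominant_b,
    missing_rate = missing_rate, sweep_region = sweep_region,
    n_genes = as.integer(n_genes), exact_af = isTRUE(exact_af),
    seed = as.integer(seed)
  ), class = "dafscreen_simconfig")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")
SENSE_CODONS <- setdiff(
  apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                    c("A", "C", "G", "T")), 1, paste, collapse = ""),
  STOP_CODONS
)

# lay out one protein-coding gene in local (plus-strand) coordinates
random_gene_layout <- function() {
  n_ex <- sample(2:3, 1)
  u5 <- sample(30:120, 1)
  u3 <- sample(30:120, 1)
  cds_lens <- sample(20:100, n_ex) * 3L
  introns <- sample(60:400, n_ex - 1)
  list(n_ex = n_ex, u5 = u5, u3 = u3, cds_lens = cds_lens,
       introns = introns,
       span = sum(cds_lens) + u5 + u3 + sum(introns))
}

# place non-overlapping gene models across chromosomes and return a
# models list compatible with gene_models() plus the coding sequences
simulate_gene_models <- function(chrom_lengths, n_genes) {
  chroms <- rep(names(chrom_lengths),
                length.out = max(n_genes, length(chrom_lengths)))[seq_len(n_genes)]
  genes <- list(); tx <- list(); coding <- list()
  counter <- 0L
  for (chr in unique(chroms)) {
    k <- sum(chroms == chr)
    len <- chrom_lengths[[chr]]
    # one gene per equal-width slot so models spread over the chromosome
    slot <- (len - 4000) %/% k
    for (j in seq_len(k)) {
      lay <- random_gene_layout()
      jitter_max <- slot - lay$span - 3000L
      if (jitter_max < 1L) next
      cursor <- 2000L + (j - 1L) * slot + sample.int(jitter_max, 1L)
      counter <- counter + 1L
      gid <- sprintf("gene%03d", counter)
      tid <- sprintf("tx%03d", counter)
      strand <- if (counter %% 2L == 0L) "-" else "+"
      # on the minus strand the genomic-left UTR is the 3' UTR
      u_left <- if (strand == "+") lay$u5 else lay$u3
      u_right <- if (strand == "+") lay$u3 else lay$u5
      # genomic CDS order follows coordinates; coding order is handled by
      # the annotator via the strand
      cds_genomic <- if (strand == "+") lay$cds_lens else rev(lay$cds_lens)
      exon_lens <- cds_genomic
      exon_lens[1] <- exon_lens[1] + u_left
      exon_lens[lay$n_ex] <- exon_lens[lay$n_ex] + u_right
      lay$exon_lens <- exon_lens
      ex_start <- integer(lay$n_ex); ex_end <- integer(lay$n_ex)
      cds_start <- integer(lay$n_ex); cds_end <- integer(lay$n_ex)
      p <- cursor
      for (e in seq_len(lay$n_ex)) {
        ex_start[e] <- p
        ex_end[e] <- p + lay$exon_lens[e] - 1L
        cds_start[e] <- if (e == 1L) p + u_left else p
        cds_end[e] <- if (e == lay$n_ex) ex_end[e] - u_right else ex_end[e]
        p <- ex_end[e] + 1L + if (e < lay$n_ex) lay$introns[e] else 0L
      }
      gene_start <- ex_start[1]; gene_end <- ex_end[lay$n_ex]
      genes[[gid]] <- data.frame(
        gene_id = gid, chrom = chr, start = gene_start, end = gene_end,
        strand = strand, stringsAsFactors = FALSE
      )
      tx[[gid]] <- list(
        transcript_id = tid, strand = strand,
        exons = data.frame(start = ex_start, end = ex_end),
        cds = data.frame(start = cds_start, end = cds_end)
      )
      n_codons <- sum(lay$cds_lens) / 3L
      coding[[gid]] <- paste0(
        "ATG",
        paste(sample(SENSE_CODONS, n_codons - 2L, replace = TRUE),
              collapse = ""),
        "TAA"
      )
    }
  }
  list(genes = do.call(rbind, unname(genes)), tx = tx, coding = coding)
}

# random genome with the planted coding sequences written over CDS spans
simulate_genome <- function(chrom_lengths, models) {
  genome <- lapply(chrom_lengths, function(len) {
    sample(c("A", "C", "G", "T"), len, replace = TRUE)
  })
  for (gid in names(models$tx)) {
    t <- models$tx[[gid]]
    chr <- models$genes$chrom[models$genes$gene_id == gid]
    cds <- t$cds
    gpos <- unlist(Map(seq.int, cds$start, cds$end))
    cod <- strsplit(models$coding[[gid]], "", fixed = TRUE)[[1]]
    if (t$strand == "+") {
      genome[[chr]][gpos] <- cod
    } else {
      genome[[chr]][rev(gpos)] <- unname(COMPLEMENT[cod])
    }
  }
  genome
}

write_fasta <- function(genome, path) {
  seqs <- Biostrings::DNAStringSet(
    vapply(genome, paste, character(1), collapse = "")
  )
  names(seqs) <- names(genome)
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}

write_gff3 <- function(models, path) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(models$genes))) {
    g <- models$genes[i, ]
    t <- models$tx[[g$gene_id]]
    lines <- c(lines,
      sprintf("%s\tdafscreen\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              g$chrom, g$start, g$end, g$strand, g$gene_id),
      sprintf("%s\tdafscreen\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              g$chrom, g$start, g$end, g$strand, t$transcript_id, g$gene_id),
      sprintf("%s\tdafscreen\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
              g$chrom, t$exons$start, t$exons$end, g$strand,
              t$transcript_id, seq_len(nrow(t$exons)), t$transcript_id),
      sprintf("%s\tdafscreen\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds%d;Parent=%s",
              g$chrom, t$cds$start, t$cds$end, g$strand,
              t$transcript_id, seq_len(nrow(t$cds)), t$transcript_id)
    )
  }
  writeLines(lines, path)
  invisible(path)
}

# positions without replacement with a minimum spacing of 6 bp, so the
# 2-in-5bp cluster filter cannot fire on simulated sites
sample_positions <- function(len, n) {
  max_x <- len - 5L * (n - 1L)
  if (max_x < n) stop("chromosome too short for ", n, " spaced sites")
  sort(sample.int(max_x, n)) + 5L * (0:(n - 1L))
}

# deterministic genotype vector hitting an exact ALT allele count
exact_genotypes <- function(k, n) {
  g <- integer(n)
  n_hom <- k %/% 2L
  if (n_hom > 0L) g[seq_len(n_hom)] <- 2L
  if (k %% 2L == 1L) g[n_hom + 1L] <- 1L
  g
}

#' Push a region's target-population frequencies toward fixation
#'
#' Emulates a selective-sweep footprint: for every site inside the region,
#' the target population's allele frequency p is replaced by p' chosen so
#' that expected heterozygosity 2p'(1-p') equals `diversity_factor` times
#' the current 2p(1-p) (moving toward the nearer fixed state), and the
#' target-population genotypes are redrawn binomially at p'. Sites outside
#' the region, and the other population, are untouched.
#'
#' @param geno dosage matrix (sites x samples).
#' @param sites site data.frame (chrom, pos) parallel to `geno` rows.
#' @param target_cols column indices of the target population.
#' @param region list with chrom, start, end (1-based inclusive bp).
#' @param diversity_factor fraction of heterozygosity retained, in (0, 1).
#' @param chrom_lengths optional named lengths for bounds checking.
#' @return List: `geno` (modified matrix), `rows` (affected row indices),
#'   `af_new` (the planted target-population frequencies).
#' @export
plant_sweep_region <- function(geno, sites, target_cols, region,
                               diversity_factor, chrom_lengths = NULL) {
  if (diversity_factor <= 0 || diversity_factor >= 1) {
    stop("diversity_factor must lie in (0, 1)")
  }
  if (!is.null(chrom_lengths)) {
    if (!region$chrom %in% names(chrom_lengths) ||
        region$start < 1 || region$end > chrom_lengths[[region$chrom]]) {
      stop("sweep region outside chromosome bounds")
    }
  }
  rows <- which(sites$chrom == region$chrom &
                  sites$pos >= region$start & sites$pos <= region$end)
  if (length(rows) == 0L) {
    return(list(geno = geno, rows = integer(0), af_new = numeric(0)))
  }
  sub <- geno[rows, target_cols, drop = FALSE]
  n_alleles <- 2 * rowSums(!is.na(sub))
  p <- ifelse(n_alleles > 0, rowSums(sub, na.rm = TRUE) / n_alleles, 0)
  het_target <- diversity_factor * p * (1 - p)
  disc <- sqrt(pmax(0, 1 - 4 * het_target))
  p_new <- ifelse(p >= 0.5, (1 + disc) / 2, (1 - disc) / 2)
  redraw <- matrix(
    stats::rbinom(length(rows) * length(target_cols), 2L, rep(p_new, length(target_cols))),
    nrow = length(rows)
  )
  geno[rows, target_cols] <- redraw
  list(geno = geno, rows = rows, af_new = p_new)
}

truth_category <- function(af_alt_a, af_alt_b, threshold = 0.5) {
  combos <- list(c("ALT", "A"), c("ALT", "B"), c("REF", "A"), c("REF", "B"))
  n <- length(af_alt_a)
  cat <- rep("NEUTRAL", n)
  allele <- rep("ALT", n)
  for (cb in combos) {
    af_f <- switch(paste(cb, collapse = ""),
      ALTA = af_alt_a, ALTB = af_alt_b,
      REFA = 1 - af_alt_a, REFB = 1 - af_alt_b)
    af_o <- switch(paste(cb, collapse = ""),
      ALTA = af_alt_b, ALTB = af_alt_a,
      REFA = 1 - af_alt_b, REFB = 1 - af_alt_a)
    cls <- classify_allele(af_f, af_o, threshold)
    hit <- cat == "NEUTRAL" & cls != "NONE"
    cat[hit] <- paste(cb[2], cls[hit], sep = "_")
    allele[hit] <- cb[1]
  }
  data.frame(planted_allele = allele, planted_category = cat,
             stringsAsFactors = FALSE)
}

#' Simulate a two-population diploid cohort with known truth
#'
#' Generates a reference genome with planted protein-coding gene models,
#' a position-sorted biallelic SNP set, per-population true allele
#' frequencies (shared Beta baseline plus planted specific/predominant
#' sites), Hardy-Weinberg genotypes (binomial(2, p) per diploid, or exact
#' allele counts when `exact_af`), an optional sweep footprint, and
#' capped per-genotype missingness. Writes VCF + FASTA + GFF3 + truth TSV
#' into `out_dir`; INFO metrics are written at passing values (QD=25,
#' MQ=60, FS=1, QUAL=100) so the emitted VCF survives its own filters.
#'
#' @param config a `dafscreen_simconfig` from [sim_config()].
#' @param out_dir output directory (created if absent).
#' @return List with `paths` (vcf, fasta, gff3, truth), `cohort`, `truth`
#'   data.frame, `models`, and `config`; invisibly.
#' @export
simulate_cohort <- function(config, out_dir) {
  stopifnot(inherits(config, "dafscreen_simconfig"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)

  models <- simulate_gene_models(config$chrom_lengths, config$n_genes)
  genome <- simulate_genome(config$chrom_lengths, models)

  # distribute sites over chromosomes proportionally to length
  lens <- config$chrom_lengths
  n_chr <- round(config$n_sites * lens / sum(lens))
  n_chr[length(n_chr)] <- config$n_sites - sum(n_chr[-length(n_chr)])
  chrom <- rep(names(lens), times = n_chr)
  pos <- unlist(lapply(names(lens), function(chr) {
    sample_positions(lens[[chr]], n_chr[[chr]])
  }))
  ref <- vapply(seq_along(pos), function(i) genome[[chrom[i]]][pos[i]],
                character(1))
  alt <- vapply(ref, function(r) {
    sample(setdiff(c("A", "C", "G", "T"), r), 1)
  }, character(1))

  n <- config$n_sites
  in_sweep <- if (!is.null(config$sweep_region)) {
    chrom == config$sweep_region$chrom &
      pos >= config$sweep_region$start & pos <= config$sweep_region$end
  } else rep(FALSE, n)

  # baseline: both populations share the same ALT frequency
  p0 <- stats::rbeta(n, config$af_beta[1], config$af_beta[2])
  af_a <- p0
  af_b <- p0

  n_cat <- round(n * c(a_spec = config$frac_specific_a,
                       b_spec = config$frac_specific_b,
                       a_pred = config$frac_predominant_a,
                       b_pred = config$frac_predominant_b))
  eligible <- which(!in_sweep)
  if (sum(n_cat) > length(eligible)) stop("too few sites outside sweep region")
  picks <- sample(eligible, sum(n_cat))
  idx_as <- picks[seq_len(n_cat["a_spec"])]
  picks <- picks[-seq_len(n_cat["a_spec"])]
  idx_bs <- picks[seq_len(n_cat["b_spec"])]
  picks <- picks[-seq_len(n_cat["b_spec"])]
  idx_ap <- picks[seq_len(n_cat["a_pred"])]
  idx_bp <- picks[-seq_len(n_cat["a_pred"])]

  plant_specific <- function(k) {
    list(focal = stats::runif(k, 0.5, 1), other = rep(0, k))
  }
  plant_predominant <- function(k) {
    focal <- 0.5 + stats::runif(k, 1e-6, 1) * 0.5
    other <- stats::runif(k, 1e-6, 1) * (focal - 0.5)
    list(focal = focal, other = other)
  }
  ps <- plant_specific(length(idx_as))
  af_a[idx_as] <- ps$focal; af_b[idx_as] <- ps$other
  ps <- plant_specific(length(idx_bs))
  af_b[idx_bs] <- ps$focal; af_a[idx_bs] <- ps$other
  pp <- plant_predominant(length(idx_ap))
  af_a[idx_ap] <- pp$focal; af_b[idx_ap] <- pp$other
  pp <- plant_predominant(length(idx_bp))
  af_b[idx_bp] <- pp$focal; af_a[idx_bp] <- pp$other

  na <- config$n_pop_a; nb <- config$n_pop_b
  if (config$exact_af) {
    planted <- sort(c(idx_as, idx_bs, idx_ap, idx_bp))
    snap <- function(af, n2) round(af * n2) / n2
    af_a <- snap(af_a, 2 * na); af_b <- snap(af_b, 2 * nb)
    # keep planted categories valid on the sample-frequency grid
    fix_pair <- function(ia, spec, focal_is_a) {
      for (i in ia) {
        nf <- if (focal_is_a) 2 * na else 2 * nb
        no <- if (focal_is_a) 2 * nb else 2 * na
        f <- if (focal_is_a) af_a[i] else af_b[i]
        o <- if (focal_is_a) af_b[i] else af_a[i]
        f <- max(f, ceiling(0.5 * nf) / nf)
        if (spec) o <- 0
        else {
          o_max <- floor((f - 0.5) * no) / no
          if (o_max < 1 / no) {
            f <- ceiling((0.5 + 1 / no) * nf) / nf
            o_max <- floor((f - 0.5) * no) / no
          }
          o <- max(min(o, o_max), 1 / no)
        }
        if (focal_is_a) { af_a[i] <<- f; af_b[i] <<- o }
        else { af_b[i] <<- f; af_a[i] <<- o }
      }
    }
    fix_pair(idx_as, TRUE, TRUE); fix_pair(idx_bs, TRUE, FALSE)
    fix_pair(idx_ap, FALSE, TRUE); fix_pair(idx_bp, FALSE, FALSE)
    geno_a <- t(vapply(round(af_a * 2 * na), exact_genotypes, integer(na),
                       n = na))
    geno_b <- t(vapply(round(af_b * 2 * nb), exact_genotypes, integer(nb),
                       n = nb))
  } else {
    geno_a <- matrix(stats::rbinom(n * na, 2L, rep(af_a, na)), nrow = n)
    geno_b <- matrix(stats::rbinom(n * nb, 2L, rep(af_b, nb)), nrow = n)
  }
  geno <- cbind(geno_a, geno_b)
  samples <- c(sprintf("A%03d", seq_len(na)), sprintf("B%03d", seq_len(nb)))
  colnames(geno) <- samples
  sites <- data.frame(chrom = chrom, pos = pos, id = ".",
                      ref = ref, alt = alt, qual = 100,
                      qd = 25, mq = 60, fs = 1,
                      mqranksum = 0, readposranksum = 0,
                      stringsAsFactors = FALSE)

  if (!is.null(config$sweep_region)) {
    target_cols <- if (config$sweep_region$target == "a") seq_len(na)
                   else na + seq_len(nb)
    sw <- plant_sweep_region(geno, sites, target_cols, config$sweep_region,
                             config$sweep_region$diversity_factor,
                             config$chrom_lengths)
    geno <- sw$geno
    if (config$sweep_region$target == "a") af_a[sw$rows] <- sw$af_new
    else af_b[sw$rows] <- sw$af_new
  }

  if (config$missing_rate > 0) {
    n_samp <- na + nb
    cap <- floor(0.10 * n_samp)   # sites must survive the missingness filter
    n_miss <- pmin(stats::rbinom(n, n_samp, config$missing_rate), cap)
    for (i in which(n_miss > 0L)) {
      geno[i, sample.int(n_samp, n_miss[i])] <- NA_integer_
    }
  }

  tc <- truth_category(af_a, af_b)
  truth <- data.frame(chrom = chrom, pos = pos,
                      planted_allele = tc$planted_allele,
                      planted_category = tc$planted_category,
                      true_af_a = af_a, true_af_b = af_b,
                      stringsAsFactors = FALSE)
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  geno <- geno[ord, , drop = FALSE]
  truth <- truth[ord, , drop = FALSE]
  rownames(sites) <- rownames(truth) <- NULL

  cohort <- structure(list(sites = sites, geno = geno, samples = samples),
                      class = "dafscreen_cohort")
  paths <- list(
    vcf = file.path(out_dir, "cohort.vcf"),
    fasta = file.path(out_dir, "genome.fa"),
    gff3 = file.path(out_dir, "genes.gff3"),
    truth = file.path(out_dir, "truth.tsv"),
    populations = file.path(out_dir, "populations.tsv")
  )
  write_vcf(cohort, paths$vcf)
  write_fasta(genome, paths$fasta)
  write_gff3(models, paths$gff3)
  utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  pops <- data.frame(sample = samples,
                     population = rep(c("POPA", "POPB"), c(na, nb)))
  utils::write.table(pops, paths$populations, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(paths = paths, cohort = cohort, truth = truth,
                 models = models, populations = pops, config = config))
}

#' Generate a cohort with planted filter violations
#'
#' Emits a small cohort in which each record is assigned a planted
#' first-cause filter outcome, cycling through passing records and
#' violations of each hard filter, the SNP-cluster rule, biallelicity and
#' missingness. Used to exercise the filter battery against enumerable
#' truth.
#'
#' @param n number of records (default 500).
#' @param n_samples diploid samples (default 20).
#' @param seed RNG seed.
#' @return List: `cohort` and `expected` (character vector of planted
#'   first-cause outcomes, `"PASS"` or a rule name).
#' @export
simulate_filter_fixture <- function(n = 500L, n_samples = 20L, seed = 1L) {
  set.seed(seed)
  kinds <- rep(c("PASS", "qd", "mq", "fs", "qual", "mq_rank_sum",
                 "read_pos_rank_sum", "cluster", "multiallelic",
                 "missingness"), length.out = n)
  pos <- 1000L + 20L * seq_len(n)   # 20 bp apart: no accidental clusters
  sites <- data.frame(
    chrom = "chr1", pos = pos, id = ".",
    ref = "A", alt = "G", qual = 100,
    qd = 25, mq = 60, fs = 1, mqranksum = 0, readposranksum = 0,
    stringsAsFactors = FALSE
  )
  geno <- matrix(stats::rbinom(n * n_samples, 2L, 0.3), nrow = n)
  colnames(geno) <- sprintf("S%03d", seq_len(n_samples))
  for (i in seq_len(n)) {
    switch(kinds[i],
      qd = { sites$qd[i] <- 1.5 },
      mq = { sites$mq[i] <- 39.0 },
      fs = { sites$fs[i] <- 60.01 },
      qual = { sites$qual[i] <- 29.0 },
      mq_rank_sum = { sites$mqranksum[i] <- -13.0 },
      read_pos_rank_sum = { sites$readposranksum[i] <- -9.0 },
      cluster = { sites$pos[i] <- sites$pos[i - 1L] + 3L },
      multiallelic = { sites$alt[i] <- "G,T" },
      missingness = {
        k <- floor(0.10 * n_samples) + 1L
        geno[i, sample.int(n_samples, k)] <- NA_integer_
      },
      PASS = NULL
    )
  }
  # a planted cluster drags its (passing) left neighbour in as well
  expected <- kinds
  clu <- which(kinds == "cluster")
  drag <- clu - 1L
  drag <- drag[kinds[drag] == "PASS"]
  expected[drag] <- "cluster"
  cohort <- structure(
    list(sites = sites, geno = geno, samples = colnames(geno)),
    class = "dafscreen_cohort"
  )
  list(cohort = cohort, expected = expected)
}

#' Compare pipeline classifications with simulation truth
#'
#' Two recall notions are reported. `recall` requires the exact planted
#' category to be called at the site. `recall_screen` requires the site
#' to be recovered by the planted focal population's screen at all
#' (specific or predominant): at finite sample size the specific /
#' predominant split at a site hinges on whether the other population's
#' *sampled* frequency is exactly zero and on the sampled delta-AF
#' crossing 0.50, so sites planted near those boundaries can be recovered
#' by the screen under the neighbouring label. Precision: fraction of
#' classified calls consistent with the true frequencies (evaluating both
#' alleles for both focal populations).
#'
#' @param classified output of [classify_sites()].
#' @param truth truth data.frame from [simulate_cohort()].
#' @return Data.frame with one row per planted category plus `overall`:
#'   n_planted, n_recovered, recall, n_called, precision.
#' @export
recovery_rates <- function(classified, truth) {
  key <- function(chrom, pos, cat) paste(chrom, pos, cat, sep = "|")
  planted <- truth[truth$planted_category != "NEUTRAL", , drop = FALSE]
  cl <- classified[classified$category != "NONE", , drop = FALSE]
  cl_key <- unique(key(cl$chrom, cl$pos, cl$category))

  # every category consistent with the true frequencies, both alleles and
  # both focal populations (a fully divergent site carries two)
  truth_all <- character(0)
  for (focal in c("A", "B")) {
    for (allele in c("ALT", "REF")) {
      af_a <- if (allele == "ALT") truth$true_af_a else 1 - truth$true_af_a
      af_b <- if (allele == "ALT") truth$true_af_b else 1 - truth$true_af_b
      af_f <- if (focal == "A") af_a else af_b
      af_o <- if (focal == "A") af_b else af_a
      cls <- classify_allele(af_f, af_o)
      hit <- cls != "NONE"
      truth_all <- c(truth_all,
                     key(truth$chrom[hit], truth$pos[hit],
                         paste(focal, cls[hit], sep = "_")))
    }
  }
  truth_all <- unique(truth_all)

  # screen-level keys: chrom|pos|focal for every call/planting
  screen_key <- function(k) sub("_(SPECIFIC|PREDOMINANT)$", "", k)
  cl_screen <- unique(screen_key(cl_key))

  cats <- sort(unique(planted$planted_category))
  rows <- lapply(c(as.list(cats), list(cats)), function(ct) {
    pl <- planted[planted$planted_category %in% ct, , drop = FALSE]
    pk <- key(pl$chrom, pl$pos, pl$planted_category)
    ck <- cl_key[sub(".*\\|", "", cl_key) %in% ct]
    data.frame(
      category = if (length(ct) > 1L) "overall" else ct,
      n_planted = nrow(pl),
      n_recovered = sum(pk %in% cl_key),
      recall = if (nrow(pl) > 0) sum(pk %in% cl_key) / nrow(pl) else NA_real_,
      recall_screen = if (nrow(pl) > 0) {
        mean(screen_key(pk) %in% cl_screen)
      } else NA_real_,
      n_called = length(ck),
      precision = if (length(ck) > 0) mean(ck %in% truth_all) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
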