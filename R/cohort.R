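#' Read a multi-sample VCF into a cohort object
#'
#' Parses a VCF 4.2 file (plain or gzipped) and returns a `dafscreen_cohort`:
#' a site table, a per-sample ALT-dosage matrix and the sample names.
#' Only SNP records are retained; records whose REF or any ALT allele is
#' longer than one base (indels, MNPs) are dropped and counted in
#' `attr(, "n_indels_dropped")`.
#'
#' Genotypes are stored as ALT-allele dosage (0, 1, 2) with `NA` for any
#' genotype containing a missing allele (half-calls such as `0/.` count as
#' missing for the whole sample) or a non-{0,1} allele index (only possible
#' at multiallelic records, which are removed by [filter_cohort()]).
#'
#' @param path path to the VCF file.
#' @return A `dafscreen_cohort` list with elements `sites` (data.frame:
#'   chrom, pos, id, ref, alt, qual, qd, mq, fs, mqranksum, readposranksum),
#'   `geno` (integer matrix, sites x samples) and `samples`.
#' @export
read_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  n_in <- nrow(fix)
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  # a record is a SNP iff REF and every comma-separated ALT allele are 1 bp
  alt_max <- vapply(strsplit(alt, ",", fixed = TRUE),
                    function(a) max(nchar(a)), integer(1))
  is_snp <- nchar(ref) == 1L & alt_max == 1L & !is.na(alt)
  n_indels <- sum(!is_snp)
  vcf <- vcf[is_snp, ]
  fix <- vcf@fix

  info_num <- function(key) {
    suppressWarnings(as.numeric(vcfR::extract.info(vcf, element = key)))
  }
  sites <- data.frame(
    chrom = fix[, "CHROM"],
    pos   = as.integer(fix[, "POS"]),
    id    = fix[, "ID"],
    ref   = fix[, "REF"],
    alt   = fix[, "ALT"],
    qual  = suppressWarnings(as.numeric(fix[, "QUAL"])),
    qd    = info_num("QD"),
    mq    = info_num("MQ"),
    fs    = info_num("FS"),
    mqranksum      = info_num("MQRankSum"),
    readposranksum = info_num("ReadPosRankSum"),
    stringsAsFactors = FALSE
  )

  gt <- vcfR::extract.gt(vcf, element = "GT")
  geno <- gt_to_dosage(gt)
  cohort <- structure(
    list(sites = sites, geno = geno, samples = colnames(gt)),
    class = "dafscreen_cohort"
  )
  attr(cohort, "n_indels_dropped") <- n_indels
  cohort
}

# GT strings -> ALT dosage matrix; anything with "." or an allele index
# other than 0/1 becomes NA
gt_to_dosage <- function(gt) {
  d <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
              dimnames = dimnames(gt))
  norm <- gsub("|", "/", gt, fixed = TRUE)
  d[norm %in% c("0/0")] <- 0L
  d[norm %in% c("0/1", "1/0")] <- 1L
  d[norm %in% c("1/1")] <- 2L
  d
}

#' Write a cohort object to a plain-text VCF 4.2 file
#'
#' Emits a minimal, position-sorted VCF with GT-only genotype columns and
#' the INFO keys the hard filters read (QD, MQ, FS, MQRankSum,
#' ReadPosRankSum). Dosages map back to `0/0`, `0/1`, `1/1` and `./.`.
#'
#' @param cohort a `dafscreen_cohort`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(cohort, path) {
  s <- cohort$sites
  ord <- order(s$chrom, s$pos)
  s <- s[ord, , drop = FALSE]
  geno <- cohort$geno[ord, , drop = FALSE]

  fmt1 <- function(x) ifelse(is.na(x), NA, formatC(x, format = "g", digits = 6))
  info_keys <- c(QD = "qd", MQ = "mq", FS = "fs",
                 MQRankSum = "mqranksum", ReadPosRankSum = "readposranksum")
  info_parts <- vapply(seq_len(nrow(s)), function(i) {
    vals <- vapply(info_keys, function(col) s[[col]][i], numeric(1))
    keep <- !is.na(vals)
    if (!any(keep)) return(".")
    paste(paste0(names(info_keys)[keep], "=", fmt1(vals[keep])), collapse = ";")
  }, character(1))

  gt_chr <- matrix("./.", nrow = nrow(geno), ncol = ncol(geno))
  gt_chr[!is.na(geno) & geno == 0L] <- "0/0"
  gt_chr[!is.na(geno) & geno == 1L] <- "0/1"
  gt_chr[!is.na(geno) & geno == 2L] <- "1/1"

  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Fisher strand bias\">",
    "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"Mapping quality rank sum\">",
    "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"Read position rank sum\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", cohort$samples), collapse = "\t")
  )
  body <- paste(
    s$chrom, s$pos, ifelse(is.na(s$id) | s$id == "", ".", s$id),
    s$ref, s$alt,
    ifelse(is.na(s$qual), ".", fmt1(s$qual)), ".", info_parts, "GT",
    apply(gt_chr, 1L, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' @export
print.dafscreen_cohort <- function(x, ...) {
  cat(sprintf("dafscreen cohort: %d sites x %d samples on %d chromosome(s)\n",
              nrow(x$sites), length(x$samples),
              length(unique(x$sites$chrom))))
  invisible(x)
}

# subset a cohort by a logical or integer site index, keeping attributes out
cohort_subset <- function(cohort, idx) {
  cohort$sites <- cohort$sites[idx, , drop = FALSE]
  rownames(cohort$sites) <- NULL
  cohort$geno <- cohort$geno[idx, , drop = FALSE]
  cohort
}
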