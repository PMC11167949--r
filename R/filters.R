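#' Default site-level hard-filter thresholds
#'
#' GATK-style hard-filter bounds for short-variant discovery: a site fails
#' when QD < 2.0, MQ < 40.0, FS > 60.0, QUAL < 30.0, MQRankSum < -12.5 or
#' ReadPosRankSum < -8.0. A metric absent from INFO never fails its rule.
#'
#' @return Named list of thresholds.
#' @export
default_filter_thresholds <- function() {
  list(qd = 2.0, mq = 40.0, fs = 60.0, qual = 30.0,
       mqranksum = -12.5, readposranksum = -8.0)
}

#' Evaluate the hard filters for every site
#'
#' Rules are evaluated in a fixed order (QD, MQ, FS, QUAL, MQRankSum,
#' ReadPosRankSum) so that the *first* violated rule can be reported for
#' filter accounting. All bounds are strict: a site with QD exactly 2.0 or
#' FS exactly 60.0 passes.
#'
#' @param sites site data.frame as in a `dafscreen_cohort`.
#' @param thresholds list as returned by [default_filter_thresholds()].
#' @return Character vector, one per site: `"PASS"` or the name of the
#'   first failing rule (`"qd"`, `"mq"`, `"fs"`, `"qual"`, `"mq_rank_sum"`,
#'   `"read_pos_rank_sum"`).
#' @export
apply_hard_filters <- function(sites, thresholds = default_filter_thresholds()) {
  n <- nrow(sites)
  fails <- cbind(
    qd   = !is.na(sites$qd)   & sites$qd   < thresholds$qd,
    mq   = !is.na(sites$mq)   & sites$mq   < thresholds$mq,
    fs   = !is.na(sites$fs)   & sites$fs   > thresholds$fs,
    qual = !is.na(sites$qual) & sites$qual < thresholds$qual,
    mq_rank_sum = !is.na(sites$mqranksum) &
      sites$mqranksum < thresholds$mqranksum,
    read_pos_rank_sum = !is.na(sites$readposranksum) &
      sites$readposranksum < thresholds$readposranksum
  )
  out <- rep("PASS", n)
  for (rule in rev(colnames(fails))) out[fails[, rule]] <- rule
  out
}

#' Flag SNPs falling in dense clusters
#'
#' Marks every SNP that lies inside any window of `window_bp` consecutive
#' bases containing at least `cluster_size` SNPs (the semantics of
#' VariantFiltration's `--cluster-size`/`--cluster-window-size`, defaults
#' 2 SNPs in 5 bp). All members of an offending cluster are flagged, not
#' just the trailing ones.
#'
#' @param chrom,pos parallel vectors of chromosome and 1-based position.
#' @param cluster_size minimum SNP count that makes a window a cluster.
#' @param window_bp window width in consecutive bases.
#' @return Logical vector: `TRUE` where the SNP is clustered.
#' @export
flag_snp_clusters <- function(chrom, pos, cluster_size = 2L, window_bp = 5L) {
  flagged <- logical(length(pos))
  for (chr in unique(chrom)) {
    i <- which(chrom == chr)
    p <- pos[i]
    if (is.unsorted(p)) stop("positions must be sorted within chromosome")
    m <- length(p)
    if (m >= cluster_size) {
      # k consecutive SNPs fit in one window iff their span <= window_bp bases
      for (s in seq_len(m - cluster_size + 1L)) {
        e <- s + cluster_size - 1L
        if (p[e] - p[s] + 1L <= window_bp) flagged[i[s:e]] <- TRUE
      }
    }
  }
  flagged
}

#' Per-site missingness and biallelicity check
#'
#' A record fails when it carries more than one ALT allele or when the
#' fraction of samples with any missing allele exceeds `max_missing`
#' (strictly greater; 7 of 73 samples missing is 0.0959 and passes, 8 of
#' 73 is 0.1096 and fails).
#'
#' @param cohort a `dafscreen_cohort`.
#' @param max_missing maximum tolerated per-site sample missing rate.
#' @return Character vector per site: `"PASS"`, `"multiallelic"` or
#'   `"missingness"` (multiallelic takes precedence).
#' @export
apply_missingness_and_biallelic <- function(cohort, max_missing = 0.10) {
  multi <- grepl(",", cohort$sites$alt, fixed = TRUE)
  miss_frac <- rowMeans(is.na(cohort$geno))
  out <- rep("PASS", nrow(cohort$sites))
  out[miss_frac > max_missing] <- "missingness"
  out[multi] <- "multiallelic"
  out
}

#' Apply the full site-filter battery to a cohort
#'
#' Runs, in first-cause order: the six hard filters, the SNP-cluster rule,
#' biallelicity, and per-site missingness. Each removed site is attributed
#' to the first rule it violates, so the report satisfies
#' `passing + sum(failing) == total`.
#'
#' @param cohort a `dafscreen_cohort`.
#' @param thresholds hard-filter thresholds.
#' @param cluster_size,window_bp SNP-cluster rule parameters.
#' @param max_missing maximum per-site sample missing rate.
#' @return List with `cohort` (surviving sites) and `report` (data.frame
#'   of rule, n_failed, plus `n_input`, `n_pass` attributes).
#' @export
filter_cohort <- function(cohort,
                          thresholds = default_filter_thresholds(),
                          cluster_size = 2L, window_bp = 5L,
                          max_missing = 0.10) {
  s <- cohort$sites
  ord <- order(s$chrom, s$pos)
  if (!identical(ord, seq_len(nrow(s)))) cohort <- cohort_subset(cohort, ord)
  s <- cohort$sites

  cause <- apply_hard_filters(s, thresholds)
  clustered <- flag_snp_clusters(s$chrom, s$pos, cluster_size, window_bp)
  cause[cause == "PASS" & clustered] <- "cluster"
  mb <- apply_missingness_and_biallelic(cohort, max_missing)
  cause[cause == "PASS" & mb != "PASS"] <- mb[cause == "PASS" & mb != "PASS"]

  rules <- c("qd", "mq", "fs", "qual", "mq_rank_sum", "read_pos_rank_sum",
             "cluster", "multiallelic", "missingness")
  report <- data.frame(
    rule = rules,
    n_failed = vapply(rules, function(r) sum(cause == r), integer(1)),
    row.names = NULL
  )
  keep <- cause == "PASS"
  out <- cohort_subset(cohort, keep)
  attr(report, "n_input") <- length(cause)
  attr(report, "n_pass") <- sum(keep)
  list(cohort = out, report = report, cause = cause)
}
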