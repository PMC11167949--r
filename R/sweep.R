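#' Per-site Weir-Cockerham (1984) variance components
#'
#' Computes, for every site, the two-population two-allele variance
#' components a (among populations), b (among individuals within
#' populations) and c (within individuals), from called genotypes only.
#' The per-site estimator is theta = a / (a + b + c); the windowed
#' "weighted" estimator sums components before taking the ratio.
#'
#' Sites where either population has no called genotype, or where fewer
#' than two genotypes are called overall (the components' denominators
#' vanish), get `NA` components and are skipped by [window_stats()].
#'
#' @param cohort a filtered `dafscreen_cohort`.
#' @param pops,pop_a,pop_b population assignment as in [site_frequencies()].
#' @return Data.frame with columns chrom, pos, a, b, c, theta.
#' @export
fst_components <- function(cohort, pops,
                           pop_a = unique(pops$population)[1],
                           pop_b = unique(pops$population)[2]) {
  idx <- pop_indices(cohort, pops, pop_a, pop_b)
  g1 <- cohort$geno[, idx$a, drop = FALSE]
  g2 <- cohort$geno[, idx$b, drop = FALSE]
  n1 <- rowSums(!is.na(g1))          # called diploids per population
  n2 <- rowSums(!is.na(g2))
  p1 <- rowSums(g1, na.rm = TRUE) / (2 * n1)
  p2 <- rowSums(g2, na.rm = TRUE) / (2 * n2)
  h1 <- rowSums(g1 == 1L, na.rm = TRUE) / n1   # observed heterozygosity
  h2 <- rowSums(g2 == 1L, na.rm = TRUE) / n2

  r <- 2
  nbar <- (n1 + n2) / r
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)

  usable <- n1 >= 1L & n2 >= 1L & nbar > 1 & nc > 0
  a <- b <- cc <- rep(NA_real_, nrow(cohort$sites))
  nb <- nbar[usable]; p_ <- pbar[usable]; h_ <- hbar[usable]
  s_ <- s2[usable]; nc_ <- nc[usable]
  a[usable] <- (nb / nc_) *
    (s_ - (1 / (nb - 1)) * (p_ * (1 - p_) - ((r - 1) / r) * s_ - h_ / 4))
  b[usable] <- (nb / (nb - 1)) *
    (p_ * (1 - p_) - ((r - 1) / r) * s_ - ((2 * nb - 1) / (4 * nb)) * h_)
  cc[usable] <- h_ / 2

  denom <- a + b + cc
  theta <- ifelse(!is.na(denom) & denom != 0, a / denom, NA_real_)
  data.frame(chrom = cohort$sites$chrom, pos = cohort$sites$pos,
             a = a, b = b, c = cc, theta = theta,
             stringsAsFactors = FALSE)
}

#' Per-site nucleotide-diversity terms for one population
#'
#' The unbiased per-site heterozygosity over called alleles:
#' 2 * c_ref * c_alt / (n * (n - 1)), with n = c_ref + c_alt. Summed over
#' the sites of a window and divided by the window length this is the
#' per-bp nucleotide diversity pi; monomorphic and uncalled sites
#' contribute 0.
#'
#' @param geno dosage matrix restricted to one population's samples.
#' @return Numeric vector of per-site diversity terms.
#' @export
pi_site_terms <- function(geno) {
  n <- 2 * rowSums(!is.na(geno))
  c_alt <- rowSums(geno, na.rm = TRUE)
  c_ref <- n - c_alt
  out <- numeric(nrow(geno))
  ok <- n >= 2
  out[ok] <- 2 * c_ref[ok] * c_alt[ok] / (n[ok] * (n[ok] - 1))
  out
}

#' Tile chromosomes with sliding windows
#'
#' Half-open windows `[start, start + window)` anchored at 0 and stepping
#' by `step`, truncated at the chromosome end; final partial windows are
#' retained (statistics are normalised by true window length).
#'
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param window,step window size and step in bp (defaults 50 kb / 10 kb).
#' @return Data.frame: chrom, start (0-based), end (exclusive).
#' @export
make_windows <- function(chrom_lengths, window = 50000L, step = 10000L) {
  out <- lapply(names(chrom_lengths), function(chr) {
    len <- chrom_lengths[[chr]]
    starts <- seq.int(0L, len - 1L, by = step)
    data.frame(chrom = chr, start = starts,
               end = pmin(starts + window, len),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Windowed FST, nucleotide diversity and pi-ratio
#'
#' For each sliding window: the weighted Weir-Cockerham FST
#' (sum(a) / sum(a + b + c) over usable sites), per-bp pi in each
#' population, and the ratio pi_b / pi_a (missing when pi_a is 0).
#' Negative window FST values are retained; they simply never reach a
#' top-quantile threshold.
#'
#' @param cohort filtered `dafscreen_cohort`.
#' @param pops,pop_a,pop_b population assignment.
#' @param chrom_lengths named chromosome lengths (bp) used for tiling.
#' @param window,step window size and step in bp.
#' @return Data.frame: chrom, start, end, n_sites, fst, pi_a, pi_b,
#'   pi_ratio.
#' @export
window_stats <- function(cohort, pops, chrom_lengths,
                         pop_a = unique(pops$population)[1],
                         pop_b = unique(pops$population)[2],
                         window = 50000L, step = 10000L) {
  comp <- fst_components(cohort, pops, pop_a, pop_b)
  idx <- pop_indices(cohort, pops, pop_a, pop_b)
  term_a <- pi_site_terms(cohort$geno[, idx$a, drop = FALSE])
  term_b <- pi_site_terms(cohort$geno[, idx$b, drop = FALSE])
  wins <- make_windows(chrom_lengths, window, step)

  pos <- cohort$sites$pos
  chrom <- cohort$sites$chrom
  res <- lapply(unique(wins$chrom), function(chr) {
    w <- wins[wins$chrom == chr, , drop = FALSE]
    on_chr <- which(chrom == chr)
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(start = pos[on_chr], width = 1L),
      IRanges::IRanges(start = w$start + 1L, end = w$end)
    )
    site_of <- on_chr[S4Vectors::queryHits(hits)]
    win_of <- S4Vectors::subjectHits(hits)
    agg <- function(x) {
      v <- rep(0, nrow(w))
      s <- tapply(x[site_of], win_of, sum, na.rm = TRUE)
      v[as.integer(names(s))] <- s
      v
    }
    usable <- !is.na(comp$a)
    w$n_sites <- tabulate(win_of, nbins = nrow(w))
    num <- agg(ifelse(usable, comp$a, 0))
    den <- agg(ifelse(usable, comp$a + comp$b + comp$c, 0))
    n_use <- tabulate(win_of[usable[site_of]], nbins = nrow(w))
    w$fst <- ifelse(n_use > 0 & den != 0, num / den, NA_real_)
    len <- w$end - w$start
    w$pi_a <- agg(term_a) / len
    w$pi_b <- agg(term_b) / len
    w$pi_ratio <- ifelse(w$pi_a > 0, w$pi_b / w$pi_a, NA_real_)
    w
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Flag jointly top-quantile windows
#'
#' Each statistic's threshold is the k-th largest value over windows
#' where it is defined, with k = floor((1 - quantile) * n) (order-
#' statistic counting: with 100 distinct-valued windows and the default
#' 0.95, exactly the top 5 qualify). A window is a sweep candidate when
#' it meets or exceeds *both* thresholds; ties at a threshold are
#' included.
#'
#' @param windows output of [window_stats()].
#' @param quantile quantile defining "top" windows (default 0.95 = top 5%).
#' @return `windows` with logical columns top_fst, top_ratio, candidate,
#'   and attributes `fst_threshold`, `ratio_threshold`.
#' @export
select_top_windows <- function(windows, quantile = 0.95) {
  ok_f <- !is.na(windows$fst)
  ok_r <- !is.na(windows$pi_ratio)
  if (sum(ok_f) < 20L || sum(ok_r) < 20L) {
    warning("fewer than 20 usable windows; quantile thresholds are unstable")
  }
  top_k_threshold <- function(x, q) {
    k <- max(1L, floor((1 - q) * length(x)))
    sort(x, decreasing = TRUE)[k]
  }
  thr_f <- top_k_threshold(windows$fst[ok_f], quantile)
  thr_r <- top_k_threshold(windows$pi_ratio[ok_r], quantile)
  windows$top_fst <- ok_f & windows$fst >= thr_f
  windows$top_ratio <- ok_r & windows$pi_ratio >= thr_r
  windows$candidate <- windows$top_fst & windows$top_ratio
  attr(windows, "fst_threshold") <- thr_f
  attr(windows, "ratio_threshold") <- thr_r
  windows
}

#' Map candidate windows to overlapping genes
#'
#' A gene is a putatively selected gene (PSG) when its span overlaps any
#' candidate window by at least one base.
#'
#' @param windows output of [select_top_windows()] (or any window frame
#'   with a logical `candidate` column).
#' @param genes gene table with columns gene_id, chrom, start, end
#'   (1-based inclusive), e.g. `gene_models(...)$genes`.
#' @return Character vector of PSG gene ids, sorted and unique.
#' @export
windows_to_genes <- function(windows, genes) {
  cand <- windows[windows$candidate, , drop = FALSE]
  if (nrow(cand) == 0L) return(character(0))
  hit <- logical(nrow(genes))
  for (chr in unique(cand$chrom)) {
    w <- cand[cand$chrom == chr, , drop = FALSE]
    gi <- which(genes$chrom == chr)
    if (length(gi) == 0L) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(start = genes$start[gi], end = genes$end[gi]),
      IRanges::IRanges(start = w$start + 1L, end = w$end)
    )
    hit[gi[unique(S4Vectors::queryHits(ov))]] <- TRUE
  }
  sort(unique(genes$gene_id[hit]))
}
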