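#' Read a sample-to-population assignment table
#'
#' @param path TSV with columns `sample` and `population`.
#' @param samples optional character vector of cohort samples; when given,
#'   the table must cover them exactly and with disjoint populations.
#' @return Data.frame with columns sample, population.
#' @export
read_populations <- function(path, samples = NULL) {
  pops <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "population") %in% names(pops))) {
    stop("population table needs columns 'sample' and 'population'")
  }
  if (anyDuplicated(pops$sample)) stop("duplicate sample in population table")
  if (!is.null(samples) && !setequal(pops$sample, samples)) {
    stop("population table does not match the cohort's samples")
  }
  pops
}

pop_indices <- function(cohort, pops, pop_a, pop_b) {
  sel <- function(p) {
    ids <- pops$sample[pops$population == p]
    if (length(ids) == 0L) stop("empty population: ", p)
    idx <- match(ids, cohort$samples)
    if (anyNA(idx)) stop("samples missing from VCF header: ",
                         paste(ids[is.na(idx)], collapse = ", "))
    idx
  }
  list(a = sel(pop_a), b = sel(pop_b))
}

#' Per-population ALT allele frequencies at every site
#'
#' Frequencies are computed over *called* alleles only: a sample with any
#' missing allele contributes nothing to numerator or denominator. Sites
#' where a population has zero called alleles get `NaN` frequency and are
#' excluded from classification downstream.
#'
#' @param cohort a filtered `dafscreen_cohort`.
#' @param pops data.frame (sample, population).
#' @param pop_a,pop_b population labels; `pop_a` maps to the `_a` columns.
#'   Default: first and second label in order of appearance.
#' @return Data.frame: chrom, pos, ref, alt, af_alt_a, af_alt_b,
#'   called_a, called_b (called allele counts, at most 2x sample count).
#' @export
site_frequencies <- function(cohort, pops,
                             pop_a = unique(pops$population)[1],
                             pop_b = unique(pops$population)[2]) {
  idx <- pop_indices(cohort, pops, pop_a, pop_b)
  g_a <- cohort$geno[, idx$a, drop = FALSE]
  g_b <- cohort$geno[, idx$b, drop = FALSE]
  called_a <- 2L * rowSums(!is.na(g_a))
  called_b <- 2L * rowSums(!is.na(g_b))
  out <- data.frame(
    chrom = cohort$sites$chrom,
    pos = cohort$sites$pos,
    ref = cohort$sites$ref,
    alt = cohort$sites$alt,
    af_alt_a = rowSums(g_a, na.rm = TRUE) / called_a,
    af_alt_b = rowSums(g_b, na.rm = TRUE) / called_b,
    called_a = called_a,
    called_b = called_b,
    stringsAsFactors = FALSE
  )
  attr(out, "pop_a") <- pop_a
  attr(out, "pop_b") <- pop_b
  out
}

#' Classify one allele for one focal population
#'
#' The screening rule: an allele is *specific* to the focal population when
#' its frequency there is at least `threshold` (default 0.50) and exactly
#' zero in the other population; it is *predominant* when its focal
#' frequency is at least `threshold`, its other-population frequency is
#' below `threshold` but nonzero, and the absolute frequency difference is
#' at least `threshold`. The two categories are disjoint by construction.
#'
#' @param af_focal,af_other allele frequency vectors.
#' @param threshold screening cutoff (0.50; see [threshold_frequency()] for
#'   its quantitative-genetics basis).
#' @return Character vector in `{"SPECIFIC", "PREDOMINANT", "NONE"}`.
#' @export
classify_allele <- function(af_focal, af_other, threshold = 0.5) {
  out <- rep("NONE", length(af_focal))
  screened <- !is.na(af_focal) & !is.na(af_other) &
    af_focal >= threshold & af_other < threshold
  out[screened & af_other == 0] <- "SPECIFIC"
  out[screened & af_other > 0 &
        abs(af_focal - af_other) >= threshold] <- "PREDOMINANT"
  out
}

#' Classify every site's REF and ALT alleles for both focal populations
#'
#' Both alleles are screened for both focal populations, so a fully
#' divergent site (ALT fixed in A, absent in B) legitimately yields an
#' `A_SPECIFIC` ALT allele and a `B_SPECIFIC` REF allele. Sites where
#' either population has zero called alleles are excluded (their count is
#' stored in `attr(, "n_undefined")`).
#'
#' @param freqs output of [site_frequencies()].
#' @param threshold screening cutoff.
#' @param keep_none keep rows classified `NONE` (default drops them).
#' @return Data.frame: chrom, pos, allele ("REF"/"ALT"), category
#'   (`A_SPECIFIC`, `A_PREDOMINANT`, `B_SPECIFIC`, `B_PREDOMINANT`,
#'   `NONE`), af_a, af_b (that allele's frequencies), delta_af, fixed
#'   (focal frequency exactly 1).
#' @export
classify_sites <- function(freqs, threshold = 0.5, keep_none = FALSE) {
  defined <- freqs$called_a > 0L & freqs$called_b > 0L
  f <- freqs[defined, , drop = FALSE]
  combos <- list(
    list(allele = "ALT", focal = "A", af_f = f$af_alt_a, af_o = f$af_alt_b),
    list(allele = "ALT", focal = "B", af_f = f$af_alt_b, af_o = f$af_alt_a),
    list(allele = "REF", focal = "A", af_f = 1 - f$af_alt_a, af_o = 1 - f$af_alt_b),
    list(allele = "REF", focal = "B", af_f = 1 - f$af_alt_b, af_o = 1 - f$af_alt_a)
  )
  parts <- lapply(combos, function(cb) {
    cls <- classify_allele(cb$af_f, cb$af_o, threshold)
    # per-allele frequencies reported in fixed a/b orientation
    if (cb$allele == "ALT") { af_a <- f$af_alt_a; af_b <- f$af_alt_b }
    else { af_a <- 1 - f$af_alt_a; af_b <- 1 - f$af_alt_b }
    data.frame(
      chrom = f$chrom, pos = f$pos,
      allele = rep_len(cb$allele, nrow(f)),
      category = ifelse(cls == "NONE", "NONE", paste(cb$focal, cls, sep = "_")),
      af_a = af_a, af_b = af_b,
      delta_af = abs(af_a - af_b),
      fixed = cls != "NONE" & cb$af_f == 1,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, parts)
  if (!keep_none) out <- out[out$category != "NONE", , drop = FALSE]
  out <- out[order(out$chrom, out$pos, out$allele, out$category), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_undefined") <- sum(!defined)
  attr(out, "pop_a") <- attr(freqs, "pop_a")
  attr(out, "pop_b") <- attr(freqs, "pop_b")
  out
}

#' Allele-frequency and delta-AF histograms per category
#'
#' Bins the focal-population allele frequency (specific categories) and
#' the absolute frequency difference (all categories) into
#' `[0.5,0.6), [0.6,0.7), [0.7,0.8), [0.8,0.9), [0.9,1.0]` — left-closed,
#' right-open, except the last bin which is closed so that fully fixed
#' alleles (AF = 1.0) land in the top bin. Fixation counts (focal AF
#' exactly 1) are reported separately.
#'
#' @param classified output of [classify_sites()].
#' @return List with `af_hist` and `delta_hist` (data.frames of category,
#'   bin, count) and `fixed` (per-category fixation counts).
#' @export
delta_af_table <- function(classified) {
  cl <- classified[classified$category != "NONE", , drop = FALSE]
  focal_af <- ifelse(startsWith(cl$category, "A_"), cl$af_a, cl$af_b)
  bins <- c("[0.5,0.6)", "[0.6,0.7)", "[0.7,0.8)", "[0.8,0.9)", "[0.9,1.0]")
  bin_of <- function(x) {
    i <- pmin(findInterval(x, c(0.5, 0.6, 0.7, 0.8, 0.9, 1 + 1e-12)), 5L)
    ifelse(i >= 1L & x >= 0.5 & x <= 1, bins[i], NA_character_)
  }
  cats <- sort(unique(cl$category))
  hist_df <- function(values) {
    b <- bin_of(values)
    do.call(rbind, lapply(cats, function(ct) {
      data.frame(category = ct, bin = bins,
                 count = as.integer(table(factor(b[cl$category == ct],
                                                 levels = bins))),
                 stringsAsFactors = FALSE)
    }))
  }
  fixed <- vapply(cats, function(ct) sum(cl$fixed[cl$category == ct]),
                  integer(1))
  list(af_hist = hist_df(focal_af),
       delta_hist = hist_df(cl$delta_af),
       fixed = data.frame(category = cats, n_fixed = unname(fixed)))
}
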