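#' Round half-up to a fixed number of decimals
#'
#' Printed summary percentages use commercial (half-up) rounding to two
#' decimals, e.g. 1,114,731 / 21,767,938 -> 5.12%. Base R's `round()`
#' rounds half to even, so ties are handled explicitly.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 2).
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

percent_of <- function(numerator, denominator) {
  round_half_up(100 * numerator / denominator, 2)
}

#' Category counts and percentages of the total SNP set
#'
#' Given per-category classified-SNP counts and the post-filter total,
#' emits each category's count and share, the combined specific +
#' predominant count per focal population, and the overall combined
#' share. Every percentage cell carries its numerator and denominator so
#' the table is self-auditing.
#'
#' @param counts named numeric vector with elements `a_specific`,
#'   `a_predominant`, `b_specific`, `b_predominant`.
#' @param total_snp_count post-filter SNP total (the denominator).
#' @return Data.frame: statistic, numerator, denominator, percent.
#' @export
category_summary <- function(counts, total_snp_count) {
  need <- c("a_specific", "a_predominant", "b_specific", "b_predominant")
  stopifnot(all(need %in% names(counts)))
  if (any(counts > total_snp_count)) {
    stop("total_snp_count smaller than a category count")
  }
  num <- c(
    a_specific = unname(counts["a_specific"]),
    a_predominant = unname(counts["a_predominant"]),
    a_combined = unname(counts["a_specific"] + counts["a_predominant"]),
    b_specific = unname(counts["b_specific"]),
    b_predominant = unname(counts["b_predominant"]),
    b_combined = unname(counts["b_specific"] + counts["b_predominant"]),
    all_combined = unname(sum(counts[need]))
  )
  out <- data.frame(
    statistic = names(num),
    numerator = unname(num),
    denominator = total_snp_count,
    percent = percent_of(unname(num), total_snp_count),
    stringsAsFactors = FALSE
  )
  audit_summary(out)
  out
}

#' Per-chromosome share of each screening category
#'
#' @param classified output of [classify_sites()] (rows with category
#'   `NONE` are ignored).
#' @return Data.frame: category, chrom, numerator (count on that
#'   chromosome), denominator (category total), percent.
#' @export
per_chromosome_summary <- function(classified) {
  cl <- classified[classified$category != "NONE", , drop = FALSE]
  tab <- table(cl$category, cl$chrom)
  totals <- rowSums(tab)
  out <- do.call(rbind, lapply(rownames(tab), function(ct) {
    data.frame(category = ct, chrom = colnames(tab),
               numerator = as.integer(tab[ct, ]),
               denominator = as.integer(totals[ct]),
               percent = percent_of(as.integer(tab[ct, ]), totals[ct]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  audit_summary(out)
  out
}

# self-consistency audit: every percentage cell must reproduce from its
# own stored numerator and denominator
audit_summary <- function(summary_df) {
  recomputed <- percent_of(summary_df$numerator, summary_df$denominator)
  if (!isTRUE(all.equal(recomputed, summary_df$percent))) {
    stop("summary table failed its percentage self-audit")
  }
  invisible(TRUE)
}

#' Overlaps between gene sets
#'
#' Computes, for every non-empty combination of the supplied sets, the
#' number of genes falling in exactly that combination (the Venn regions)
#' and the size of the combination's intersection, plus the overall
#' union. Duplicate ids within a set are dropped with a logged count.
#'
#' @param sets named list of character vectors (e.g. candidate genes,
#'   PSGs, a curated gene list).
#' @return List: `regions` (data.frame combo/n_exact/n_intersection with
#'   member lists in `attr(, "members")`), `union_size`,
#'   `n_duplicates_dropped`.
#' @export
overlap_report <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2L, !is.null(names(sets)))
  n_dup <- sum(vapply(sets, function(s) length(s) - length(unique(s)),
                      integer(1)))
  sets <- lapply(sets, unique)
  universe <- sort(unique(unlist(sets)))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL, names(sets)))
  k <- length(sets)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1, , drop = FALSE]
  names(combos) <- names(sets)
  members <- list()
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    inc <- unlist(combos[i, ])
    combo_name <- paste(names(sets)[inc], collapse = "&")
    exact <- rowSums(member[, inc, drop = FALSE]) == sum(inc) &
      rowSums(member[, !inc, drop = FALSE]) == 0
    inter <- rowSums(member[, inc, drop = FALSE]) == sum(inc)
    members[[combo_name]] <<- universe[inter]
    data.frame(combo = combo_name, n_exact = sum(exact),
               n_intersection = sum(inter), stringsAsFactors = FALSE)
  })
  regions <- do.call(rbind, rows)
  attr(regions, "members") <- members
  list(regions = regions, union_size = length(universe),
       n_duplicates_dropped = n_dup)
}
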