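gff_attr <- function(attributes, key) {
  pat <- paste0("(^|;)\\s*", key, "=([^;]+)")
  has <- grepl(pat, attributes)
  res <- rep(NA_character_, length(attributes))
  res[has] <- sub(paste0(".*", pat, ".*"), "\\2", attributes[has])
  res
}

#' Load gene models from a GFF3 file
#'
#' Reads a gene -> mRNA -> exon/CDS hierarchy (1-based inclusive
#' coordinates). When a gene carries several transcripts, the one with the
#' greatest summed exon length is retained for effect calls, so
#' annotations are deterministic. CDS segments must lie inside the
#' transcript's exons.
#'
#' @param path GFF3 file.
#' @return List with `genes` (data.frame: gene_id, chrom, start, end,
#'   strand) and `tx` (named list per gene_id: strand, exons and cds
#'   data.frames sorted by start).
#' @export
gene_models <- function(path) {
  g <- ape::read.gff(path)
  g$attributes <- as.character(g$attributes)
  g$seqid <- as.character(g$seqid)
  g$strand <- as.character(g$strand)
  g$type <- as.character(g$type)

  genes <- g[g$type == "gene", , drop = FALSE]
  gene_df <- data.frame(
    gene_id = gff_attr(genes$attributes, "ID"),
    chrom = genes$seqid, start = genes$start, end = genes$end,
    strand = genes$strand, stringsAsFactors = FALSE
  )
  mrna <- g[g$type %in% c("mRNA", "transcript"), , drop = FALSE]
  mrna_id <- gff_attr(mrna$attributes, "ID")
  mrna_parent <- gff_attr(mrna$attributes, "Parent")
  feats <- g[g$type %in% c("exon", "CDS"), , drop = FALSE]
  feat_parent <- gff_attr(feats$attributes, "Parent")

  tx <- list()
  for (i in seq_len(nrow(gene_df))) {
    gid <- gene_df$gene_id[i]
    tids <- mrna_id[mrna_parent == gid]
    if (length(tids) == 0L) next
    best <- NULL; best_len <- -1
    for (tid in tids) {
      f <- feats[feat_parent == tid, , drop = FALSE]
      ex <- f[f$type == "exon", c("start", "end")]
      cds <- f[f$type == "CDS", c("start", "end")]
      ex <- ex[order(ex$start), , drop = FALSE]
      cds <- cds[order(cds$start), , drop = FALSE]
      if (nrow(cds) > 0L) {
        inside <- vapply(seq_len(nrow(cds)), function(k) {
          any(cds$start[k] >= ex$start & cds$end[k] <= ex$end)
        }, logical(1))
        if (!all(inside)) stop("CDS outside exon in transcript ", tid)
      }
      len <- sum(ex$end - ex$start + 1L)
      if (len > best_len) {
        best_len <- len
        best <- list(transcript_id = tid, strand = gene_df$strand[i],
                     exons = ex, cds = cds)
      }
    }
    tx[[gid]] <- best
  }
  list(genes = gene_df, tx = tx)
}

#' Load a reference genome FASTA
#'
#' @param path FASTA file with one record per chromosome.
#' @return A named `Biostrings::DNAStringSet`.
#' @export
load_genome <- function(path) {
  fa <- Biostrings::readDNAStringSet(path)
  names(fa) <- sub("\\s.*$", "", names(fa))
  fa
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

EFFECT_PRECEDENCE <- c(
  stop_gained = 1L, missense = 2L, synonymous = 3L, splice_region = 4L,
  five_prime_utr = 5L, three_prime_utr = 6L, intron = 7L,
  upstream = 8L, downstream = 9L, intergenic = 10L
)

# genomic positions (coding order) of the codon containing cds offset
# `off` (0-based); segs sorted by start, strand "+" or "-"
codon_genomic_pos <- function(off, segs, strand) {
  codon_start <- (off %/% 3L) * 3L
  lens <- segs$end - segs$start + 1L
  order_idx <- if (strand == "+") seq_len(nrow(segs)) else rev(seq_len(nrow(segs)))
  vapply(codon_start + 0:2, function(j) {
    rem <- j
    for (k in order_idx) {
      if (rem < lens[k]) {
        return(if (strand == "+") segs$start[k] + rem else segs$end[k] - rem)
      }
      rem <- rem - lens[k]
    }
    NA_integer_
  }, numeric(1))
}

# effect of a SNP relative to one gene model; chromseq is the chromosome
# as a character vector
effect_for_gene <- function(pos, ref, alt, gene, tx, chromseq,
                            flank = 1000L, splice_intron = 8L,
                            splice_exon = 3L) {
  strand <- gene$strand
  if (pos < gene$start) {
    return(list(effect = if (strand == "+") "upstream" else "downstream",
                codon_change = NA_character_))
  }
  if (pos > gene$end) {
    return(list(effect = if (strand == "+") "downstream" else "upstream",
                codon_change = NA_character_))
  }
  if (is.null(tx)) return(list(effect = "intron", codon_change = NA_character_))
  ex <- tx$exons; cds <- tx$cds

  in_cds <- nrow(cds) > 0L && any(pos >= cds$start & pos <= cds$end)
  if (in_cds) {
    if (chromseq[pos] != ref) {
      stop(sprintf("REF mismatch at %d: VCF %s, FASTA %s",
                   pos, ref, chromseq[pos]))
    }
    lens <- cds$end - cds$start + 1L
    order_idx <- if (strand == "+") seq_len(nrow(cds)) else rev(seq_len(nrow(cds)))
    off <- 0L
    for (k in order_idx) {
      if (pos >= cds$start[k] && pos <= cds$end[k]) {
        off <- off + if (strand == "+") pos - cds$start[k] else cds$end[k] - pos
        break
      }
      off <- off + lens[k]
    }
    gpos <- codon_genomic_pos(off, cds, strand)
    base_at <- function(p) {
      b <- chromseq[p]
      if (strand == "+") b else unname(COMPLEMENT[b])
    }
    ref_codon <- paste(vapply(gpos, base_at, character(1)), collapse = "")
    within <- off %% 3L
    alt_base <- if (strand == "+") alt else unname(COMPLEMENT[alt])
    alt_codon <- ref_codon
    substr(alt_codon, within + 1L, within + 1L) <- alt_base
    code <- Biostrings::GENETIC_CODE
    ref_aa <- unname(code[ref_codon]); alt_aa <- unname(code[alt_codon])
    if (is.na(ref_aa) || is.na(alt_aa)) {
      return(list(effect = "synonymous", codon_change = NA_character_))
    }
    eff <- if (alt_aa == "*" && ref_aa != "*") "stop_gained"
           else if (alt_aa == ref_aa) "synonymous" else "missense"
    return(list(effect = eff,
                codon_change = sprintf("%s/%s|%s/%s",
                                       ref_codon, alt_codon, ref_aa, alt_aa)))
  }

  exon_i <- which(pos >= ex$start & pos <= ex$end)
  if (length(exon_i) > 0L) {
    i <- exon_i[1]
    # distance to a splice junction: exon edges that border an intron
    d <- Inf
    if (i > 1L) d <- min(d, pos - ex$start[i])
    if (i < nrow(ex)) d <- min(d, ex$end[i] - pos)
    if (is.finite(d) && d < splice_exon) {
      return(list(effect = "splice_region", codon_change = NA_character_))
    }
    if (nrow(cds) == 0L) {
      return(list(effect = "intron", codon_change = NA_character_))
    }
    cds_min <- min(cds$start); cds_max <- max(cds$end)
    before <- pos < cds_min
    eff <- if ((strand == "+") == before) "five_prime_utr" else "three_prime_utr"
    return(list(effect = eff, codon_change = NA_character_))
  }

  # intronic within the transcript (or between transcript and gene bounds)
  d <- Inf
  if (any(ex$end < pos)) d <- min(d, pos - max(ex$end[ex$end < pos]))
  if (any(ex$start > pos)) d <- min(d, min(ex$start[ex$start > pos]) - pos)
  eff <- if (is.finite(d) && d <= splice_intron) "splice_region" else "intron"
  list(effect = eff, codon_change = NA_character_)
}

#' Annotate SNPs with genes and functional effect classes
#'
#' Each SNP is assigned every gene whose extended span (gene body plus
#' `flank` bp on both sides, the "-ud 1000" convention) covers it; its
#' effect class is the highest-precedence class over those genes
#' (stop_gained > missense > synonymous > splice_region > 5'/3' UTR >
#' intron > upstream/downstream), or `intergenic` when no gene is in
#' range. Coding effects are computed on the coding strand from the
#' longest transcript; splice regions are the first 2 intronic bases
#' (donor/acceptor) plus intronic bases 3-8 and exonic bases within 3 bp
#' of a junction.
#'
#' @param sites data.frame with chrom, pos, ref, alt (e.g.
#'   `cohort$sites`).
#' @param models output of [gene_models()].
#' @param genome `DNAStringSet` from [load_genome()].
#' @param flank upstream/downstream window in bp (default 1000).
#' @return Data.frame: chrom, pos, ref, alt, gene_ids (comma-joined,
#'   empty for intergenic), effect, codon_change.
#' @export
annotate_sites <- function(sites, models, genome, flank = 1000L) {
  genes <- models$genes
  n <- nrow(sites)
  effect <- character(n); gene_ids <- character(n)
  codon <- rep(NA_character_, n)

  for (chr in unique(sites$chrom)) {
    si <- which(sites$chrom == chr)
    gi <- which(genes$chrom == chr)
    chromseq <- strsplit(as.character(genome[[chr]]), "", fixed = TRUE)[[1]]
    if (length(gi) > 0L) {
      ov <- IRanges::findOverlaps(
        IRanges::IRanges(start = sites$pos[si], width = 1L),
        IRanges::IRanges(start = pmax(genes$start[gi] - flank, 1L),
                         end = genes$end[gi] + flank)
      )
      hit_site <- S4Vectors::queryHits(ov)
      hit_gene <- gi[S4Vectors::subjectHits(ov)]
    } else {
      hit_site <- integer(0); hit_gene <- integer(0)
    }
    for (k in seq_along(si)) {
      idx <- si[k]
      gset <- hit_gene[hit_site == k]
      if (length(gset) == 0L) {
        effect[idx] <- "intergenic"; gene_ids[idx] <- ""
        next
      }
      best_eff <- "intergenic"; best_rank <- EFFECT_PRECEDENCE[["intergenic"]]
      best_codon <- NA_character_
      for (g in gset) {
        gid <- genes$gene_id[g]
        res <- effect_for_gene(sites$pos[idx], sites$ref[idx],
                               sites$alt[idx],
                               genes[g, , drop = FALSE], models$tx[[gid]],
                               chromseq, flank = flank)
        r <- EFFECT_PRECEDENCE[[res$effect]]
        if (r < best_rank) {
          best_rank <- r; best_eff <- res$effect
          best_codon <- res$codon_change
        }
      }
      effect[idx] <- best_eff
      codon[idx] <- best_codon
      gene_ids[idx] <- paste(sort(genes$gene_id[gset]), collapse = ",")
    }
  }
  data.frame(chrom = sites$chrom, pos = sites$pos, ref = sites$ref,
             alt = sites$alt, gene_ids = gene_ids, effect = effect,
             codon_change = codon, stringsAsFactors = FALSE)
}

#' Aggregate annotated, classified SNPs into a per-gene candidate table
#'
#' Joins a classification table to an annotation table on (chrom, pos) and
#' counts, per gene, SNPs by screening category and by effect class. A SNP
#' annotated to several genes increments each of them. The union of genes
#' over all four categories is the candidate gene set.
#'
#' @param classified output of [classify_sites()].
#' @param annotated output of [annotate_sites()].
#' @return List: `by_category` and `by_effect` (long count data.frames)
#'   and `candidate_genes` (sorted character vector).
#' @export
aggregate_candidate_genes <- function(classified, annotated) {
  cl <- classified[classified$category != "NONE", , drop = FALSE]
  if (nrow(cl) == 0L) {
    empty <- data.frame(gene_id = character(0), key = character(0),
                        n = integer(0))
    names(empty)[2] <- "category"
    empty2 <- empty; names(empty2)[2] <- "effect"
    return(list(by_category = empty, by_effect = empty2,
                candidate_genes = character(0)))
  }
  key <- function(chrom, pos) paste(chrom, pos, sep = ":")
  ann_key <- key(annotated$chrom, annotated$pos)
  m <- match(key(cl$chrom, cl$pos), ann_key)
  cl$gene_ids <- annotated$gene_ids[m]
  cl$effect <- annotated$effect[m]

  expand <- function(df) {
    gl <- strsplit(df$gene_ids, ",", fixed = TRUE)
    reps <- lengths(gl)
    keep <- reps > 0L & df$gene_ids != ""
    data.frame(gene_id = unlist(gl[keep]),
               category = rep(df$category[keep], reps[keep]),
               effect = rep(df$effect[keep], reps[keep]),
               stringsAsFactors = FALSE)
  }
  long <- expand(cl)
  by_category <- as.data.frame(table(gene_id = long$gene_id,
                                     category = long$category),
                               stringsAsFactors = FALSE)
  names(by_category)[3] <- "n"
  by_category <- by_category[by_category$n > 0L, , drop = FALSE]
  by_effect <- as.data.frame(table(gene_id = long$gene_id,
                                   effect = long$effect),
                             stringsAsFactors = FALSE)
  names(by_effect)[3] <- "n"
  by_effect <- by_effect[by_effect$n > 0L, , drop = FALSE]
  rownames(by_category) <- rownames(by_effect) <- NULL
  list(by_category = by_category, by_effect = by_effect,
       candidate_genes = sort(unique(long$gene_id)))
}
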