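#' Filter 5'-end tag records
#'
#' Keeps tags with a single alignment, no soft-clipped bases at the 5'
#' end, and soft-clipping over at most 10% of the read length —
#' removing reads whose mapped 5' position is unreliable as a
#' transcription-initiation signal.
#'
#' @param tags data.frame of 5'-end tag records with columns
#'   `n_alignments`, `softclip_5prime`, `softclip_total_fraction`.
#' @param max_softclip_fraction maximum tolerated soft-clipped fraction
#'   of the read length (default 0.10, inclusive).
#' @return The retained rows, with attribute `"report"` tallying
#'   removals per rule.
#' @export
filter_tss_reads <- function(tags, max_softclip_fraction = 0.10) {
  multi <- tags$n_alignments != 1L
  clip5 <- !multi & tags$softclip_5prime > 0L
  clipf <- !multi & !clip5 &
    tags$softclip_total_fraction > max_softclip_fraction
  keep <- !(multi | clip5 | clipf)
  out <- tags[keep, , drop = FALSE]
  attr(out, "report") <- c(input = nrow(tags),
                           multi_aligned = sum(multi),
                           softclip_5prime = sum(clip5),
                           softclip_fraction = sum(clipf),
                           kept = nrow(out))
  out
}

#' Internal 5'-end tag counts per gene
#'
#' Counts, for every gene and sample, the tags whose 5' end falls
#' within the gene body on the matching strand at a gene-relative
#' offset of at least `exclusion` bp (measured from the TSS in the
#' direction of transcription). Excluding the first 200 bp removes
#' signal from the annotated promoter, leaving internal (potentially
#' cryptic) initiation. The boundary is inclusive: a tag exactly at
#' `+exclusion` is counted.
#'
#' @param tags filtered tag data.frame (columns chromosome,
#'   five_prime_position, strand, sample_id).
#' @param genome a [genome_model()].
#' @param exclusion bp excluded at the 5' end of each gene (default
#'   200).
#' @return Integer matrix, genes by samples (all genes, zero-filled).
#' @export
internal_counts <- function(tags, genome, exclusion = 200L) {
  stopifnot(inherits(genome, "genome_model"))
  gb <- gene_body_bounds(genome)
  samples <- sort(unique(tags$sample_id))
  out <- matrix(0L, nrow(gb), length(samples),
                dimnames = list(gb$gene_id, samples))
  if (!nrow(tags)) return(out)
  gr_genes <- GenomicRanges::GRanges(
    gb$chromosome,
    IRanges::IRanges(gb$start + 1L, gb$end),  # 1-based inclusive
    strand = gb$strand)
  gr_tags <- GenomicRanges::GRanges(
    tags$chromosome,
    IRanges::IRanges(tags$five_prime_position + 1L, width = 1L),
    strand = tags$strand)
  ov <- GenomicRanges::findOverlaps(gr_tags, gr_genes)
  ti <- S4Vectors::queryHits(ov)
  gi <- S4Vectors::subjectHits(ov)
  off <- ifelse(gb$strand[gi] == "+",
                tags$five_prime_position[ti] - gb$tss[gi],
                gb$tss[gi] - tags$five_prime_position[ti])
  keep <- off >= exclusion
  if (any(keep)) {
    tab <- table(factor(gb$gene_id[gi[keep]], levels = gb$gene_id),
                 factor(tags$sample_id[ti[keep]], levels = samples))
    out[] <- out + as.integer(tab)
  }
  out
}

#' Call genes with increased internal transcription initiation
#'
#' Differential test of internal 5'-end tag counts between a reference
#' and a mutant condition: library sizes are normalised by
#' median-of-ratios size factors over genes, each gene is tested with
#' the negative-binomial Wald test, p-values are Benjamini-Hochberg
#' adjusted, and a gene is called dependent when its log2 fold change
#' (mutant over reference) is positive and its adjusted p-value is
#' below `padj_threshold`. Genes with zero counts in every sample are
#' dropped before testing.
#'
#' @param count_table integer matrix genes by samples (e.g. from
#'   [internal_counts()]).
#' @param conditions named vector (or vector aligned with the columns)
#'   assigning each sample to a condition.
#' @param condition_ref,condition_alt the reference (e.g. wild type)
#'   and alternative (e.g. Set2 deletion) condition labels; defaults to
#'   the first and second condition encountered.
#' @param padj_threshold adjusted p-value threshold (default 0.1).
#' @return data.frame: gene_id, base_mean, log2_fold_change, wald_p,
#'   adjusted_p, set2_dependent.
#' @export
call_set2_dependent <- function(count_table, conditions,
                                condition_ref = NULL, condition_alt = NULL,
                                padj_threshold = 0.1) {
  m <- as.matrix(count_table)
  if (is.null(names(conditions))) names(conditions) <- colnames(m)
  conditions <- conditions[colnames(m)]
  lev <- unique(conditions)
  if (length(lev) != 2) stop("exactly two conditions required")
  if (is.null(condition_ref)) condition_ref <- lev[1]
  if (is.null(condition_alt)) condition_alt <- setdiff(lev, condition_ref)
  nz <- rowSums(m) > 0
  if (any(!nz))
    message("call_set2_dependent: dropping ", sum(!nz), " all-zero gene(s)")
  mm <- m[nz, , drop = FALSE]
  sf <- size_factors(mm)
  A <- mm[, conditions == condition_ref, drop = FALSE]
  B <- mm[, conditions == condition_alt, drop = FALSE]
  fA <- matrix(sf[conditions == condition_ref], nrow(mm), ncol(A), byrow = TRUE)
  fB <- matrix(sf[conditions == condition_alt], nrow(mm), ncol(B), byrow = TRUE)
  res <- nb_wald_test(A, B, fA, fB)
  padj <- p.adjust(res$wald_p, method = "BH")
  data.frame(gene_id = rownames(mm),
             base_mean = res$base_mean,
             log2_fold_change = res$log2_fold_change,
             wald_p = res$wald_p,
             adjusted_p = padj,
             set2_dependent = res$log2_fold_change > 0 &
               padj < padj_threshold,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Median-of-ratios size factors
#'
#' Per-sample scaling factors: the median, over genes with a positive
#' geometric mean, of each sample's counts divided by the per-gene
#' geometric mean across samples.
#'
#' @param m counts matrix, genes by samples.
#' @return named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(m) {
  m <- as.matrix(m)
  logm <- log(m)
  geo <- rowMeans(logm)
  use <- is.finite(geo)
  if (!any(use)) stop("no gene has positive counts in every sample")
  sf <- apply(m[use, , drop = FALSE], 2, function(col)
    exp(median(log(col) - geo[use])))
  if (any(!is.finite(sf) | sf <= 0))
    stop("degenerate size factor; check the count table")
  sf
}
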