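#' Fragment filtering configuration
#'
#' Size, duplicate and alignment-quality rules that reduce aligned read
#' pairs to mono-nucleosomal fragments. Fragments longer than
#' `max_fragment` are assumed not to derive from a mono-nucleosome and
#' are removed. The lower bound differs by context: `min_fragment`
#' (default 130 bp) applies to IP lanes from multiplexed experiments,
#' while input lanes use the wider `input_min_fragment` floor (default
#' 100 bp) so that strains whose chromatin is more MNase-sensitive, and
#' therefore yields shorter protected fragments, are not censored in
#' the normalisation reference. Stacks of identical fragments beyond
#' `duplicate_cap` copies are treated as PCR duplicates.
#'
#' @param max_fragment maximum fragment length in bp (default 220).
#' @param min_fragment minimum length for IP lanes in multiplex mode;
#'   `NA` disables the lower bound (pairwise-comparison mode).
#' @param input_min_fragment minimum length applied to input lanes.
#' @param duplicate_cap copies retained per distinct fragment.
#' @param min_mapq minimum mapping quality for a pair to count as
#'   confidently placed.
#' @return A `filter_config` object.
#' @export
filter_config <- function(max_fragment = 220L, min_fragment = 130L,
                          input_min_fragment = 100L, duplicate_cap = 2L,
                          min_mapq = 30L) {
  if (!is.na(min_fragment) && min_fragment >= max_fragment)
    stop("min_fragment must be smaller than max_fragment")
  if (!is.na(input_min_fragment) && input_min_fragment >= max_fragment)
    stop("input_min_fragment must be smaller than max_fragment")
  structure(list(max_fragment = as.integer(max_fragment),
                 min_fragment = as.integer(min_fragment),
                 input_min_fragment = as.integer(input_min_fragment),
                 duplicate_cap = as.integer(duplicate_cap),
                 min_mapq = as.integer(min_mapq)),
            class = "filter_config")
}

cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(NA_integer_)
    ops <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    len <- as.integer(sub("[A-Z=]$", "", ops))
    op <- sub("^\\d+", "", ops)
    sum(len[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Load aligned read pairs from SAM/BAM
#'
#' Reads a paired-end alignment file and yields one record per primary
#' mate pair in 0-based half-open genomic coordinates. A pair is marked
#' `unique` when neither mate has secondary-alignment records, and
#' `proper_convergent` when the two mates are inward-facing (FR: the
#' leftmost mate on the plus strand, its mate on the minus strand).
#' Unpaired or malformed records are tallied and skipped.
#'
#' @param path SAM or BAM file (SAM is converted on the fly).
#' @param sample_id sample label attached to each pair.
#' @return data.frame of aligned pairs: chromosome, start, end,
#'   proper_convergent, unique, mapping_quality (min over mates),
#'   sample_id, qname; attribute `"skipped"` holds the tally of records
#'   that could not be paired.
#' @export
load_aligned_pairs <- function(path, sample_id = "sample") {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = ".bam")
    path <- Rsamtools::asBam(path, sub("\\.bam$", "", dest),
                             overwrite = TRUE, indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "mapq", "cigar"),
    flag = Rsamtools::scanBamFlag(isPaired = TRUE, isUnmappedQuery = FALSE))
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  flag <- b$flag
  secondary <- bitwAnd(flag, 256L) > 0L
  supplementary <- bitwAnd(flag, 2048L) > 0L
  has_secondary <- unique(b$qname[secondary])
  primary <- !secondary & !supplementary
  df <- data.frame(qname = b$qname, rname = as.character(b$rname),
                   strand = as.character(b$strand), pos = b$pos,
                   mapq = b$mapq,
                   width = cigar_ref_width(b$cigar),
                   first = bitwAnd(flag, 64L) > 0L,
                   stringsAsFactors = FALSE)[primary, ]
  df <- df[!is.na(df$pos) & !is.na(df$width), ]
  cnt <- table(df$qname)
  paired <- names(cnt)[cnt == 2L]
  skipped <- nrow(df) - 2L * length(paired)
  if (skipped > 0)
    message("load_aligned_pairs: skipped ", skipped,
            " record(s) without a usable mate")
  df <- df[df$qname %in% paired, ]
  df <- df[order(df$qname, !df$first), ]
  i1 <- seq(1L, nrow(df), by = 2L)
  i2 <- i1 + 1L
  left <- ifelse(df$pos[i1] <= df$pos[i2], i1, i2)
  right <- ifelse(df$pos[i1] <= df$pos[i2], i2, i1)
  conv <- df$rname[i1] == df$rname[i2] &
    df$strand[left] == "+" & df$strand[right] == "-"
  out <- data.frame(
    chromosome = df$rname[i1],
    start = pmin(df$pos[i1], df$pos[i2]) - 1L,
    end = pmax(df$pos[i1] + df$width[i1], df$pos[i2] + df$width[i2]) - 1L,
    proper_convergent = conv,
    unique = !(df$qname[i1] %in% has_secondary),
    mapping_quality = pmin(df$mapq[i1], df$mapq[i2]),
    sample_id = sample_id,
    qname = df$qname[i1],
    stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  out
}

#' Filter aligned pairs down to mono-nucleosomal fragments
#'
#' Keeps pairs that are uniquely and unambiguously aligned (`unique`
#' and mapping quality at least `cfg$min_mapq`), inward-facing
#' (`proper_convergent`), and whose fragment length lies within the
#' mono-nucleosomal size window. The effective lower bound is
#' `cfg$input_min_fragment` for input lanes and `cfg$min_fragment`
#' otherwise; either may be `NA` to disable it.
#'
#' @param pairs data.frame of aligned pairs (as from
#'   [load_aligned_pairs()], or a simulator fragment table with the same
#'   coordinate columns; missing QC columns are treated as passing).
#' @param cfg a [filter_config()].
#' @param is_input is this a chromatin-input lane?
#' @return data.frame of retained fragments (chromosome, start, end,
#'   sample_id, copies) with attribute `"report"`: a named vector of
#'   removal tallies per rule (applied in sequence).
#' @export
filter_fragments <- function(pairs, cfg = filter_config(), is_input = FALSE) {
  stopifnot(inherits(cfg, "filter_config"))
  n0 <- nrow(pairs)
  uniq <- if ("unique" %in% names(pairs)) pairs$unique else rep(TRUE, n0)
  mq <- if ("mapping_quality" %in% names(pairs))
    pairs$mapping_quality >= cfg$min_mapq else rep(TRUE, n0)
  conv <- if ("proper_convergent" %in% names(pairs))
    pairs$proper_convergent else rep(TRUE, n0)
  len <- pairs$end - pairs$start
  eff_min <- if (is_input) cfg$input_min_fragment else cfg$min_fragment
  too_long <- len > cfg$max_fragment
  too_short <- if (is.na(eff_min)) rep(FALSE, n0) else len < eff_min
  report <- c(input = n0,
              not_unique = sum(!uniq),
              low_mapq = sum(uniq & !mq),
              not_convergent = sum(uniq & mq & !conv),
              too_long = sum(uniq & mq & conv & too_long),
              too_short = sum(uniq & mq & conv & !too_long & too_short))
  keep <- uniq & mq & conv & !too_long & !too_short
  out <- pairs[keep, , drop = FALSE]
  if (!"copies" %in% names(out)) out$copies <- rep(1L, nrow(out))
  report <- c(report, kept = nrow(out))
  attr(out, "report") <- report
  out
}

#' Cap PCR-duplicate stacks of identical fragments
#'
#' Fragments sharing the same first and last genomic positions (and
#' sample) beyond `cap` copies are treated as PCR duplicates: each
#' distinct `(chromosome, start, end, sample_id)` retains at most `cap`
#' copies and the excess is removed. With `mode = "drop"` the whole
#' stack is discarded instead whenever it exceeds the cap.
#'
#' @param fragments fragment data.frame with a `copies` column (absent
#'   means one copy per row).
#' @param cap maximum retained copies per distinct fragment (default 2).
#' @param mode `"cap"` (default: keep `cap` copies) or `"drop"`
#'   (discard over-duplicated stacks entirely).
#' @return data.frame with one row per distinct fragment and the
#'   retained `copies`; attribute `"removed"` counts removed copies.
#' @export
deduplicate <- function(fragments, cap = 2L, mode = c("cap", "drop")) {
  mode <- match.arg(mode)
  if (!"copies" %in% names(fragments)) fragments$copies <- 1L
  key <- paste(fragments$chromosome, fragments$start, fragments$end,
               fragments$sample_id, sep = "\r")
  tot <- rowsum(as.numeric(fragments$copies), key)
  first <- !duplicated(key)
  out <- fragments[first, c("chromosome", "start", "end", "sample_id"),
                   drop = FALSE]
  observed <- as.integer(tot[match(key[first], rownames(tot)), 1])
  retained <- if (mode == "cap") pmin(observed, as.integer(cap)) else
    ifelse(observed > cap, 0L, observed)
  out$copies <- retained
  removed <- sum(observed) - sum(retained)
  out <- out[out$copies > 0L, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- removed
  out
}

#' Nucleosome midpoints from fragments
#'
#' The nucleosome midpoint is approximated as the centre of the genomic
#' locus intercepted by the read pair: for a fragment `[start, end)` in
#' 0-based half-open coordinates, `midpoint = floor((start + end - 1) /
#' 2)` (floor tie-break for even lengths).
#'
#' @param fragments fragment data.frame (`copies` column optional).
#' @return data.frame: chromosome, midpoint, sample_id, multiplicity.
#' @export
midpoints <- function(fragments) {
  if (!"copies" %in% names(fragments)) fragments$copies <- 1L
  data.frame(chromosome = fragments$chromosome,
             midpoint = (fragments$start + fragments$end - 1L) %/% 2L,
             sample_id = fragments$sample_id,
             multiplicity = fragments$copies,
             stringsAsFactors = FALSE)
}
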