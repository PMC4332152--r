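#' Demultiplex barcoded paired-end reads
#'
#' Assigns each read pair to the unique barcode within `max_mismatches`
#' of the 6-mer prefix of read 1, trims the barcode (plus
#' `trim_extra` ligation bases, if configured) from read 1, and writes
#' per-sample paired FASTQ files plus an `undetermined` pair for the
#' audit trail. Assignment is unambiguous by construction: the call
#' refuses configurations in which two barcodes lie within
#' `2 * max_mismatches` of each other.
#'
#' @param fastq1,fastq2 paths to the pooled read-1 / read-2 FASTQ files.
#' @param barcode_map a [barcode_map()].
#' @param max_mismatches maximum Hamming distance tolerated between the
#'   read-1 prefix and a barcode (default 0).
#' @param outdir output directory for per-sample FASTQ (default: a
#'   fresh temporary directory).
#' @param trim_extra additional bases trimmed after the barcode.
#' @param lane_id label for the resulting lane counts.
#' @return A `lane_counts` object: list with `lane_id`, `counts` (named
#'   integer vector per sample), `unassigned`, `total` and `files`
#'   (data.frame sample_id / R1 / R2 paths).
#' @export
demultiplex_pairs <- function(fastq1, fastq2, barcode_map,
                              max_mismatches = 0L, outdir = tempfile("demux"),
                              trim_extra = 0L, lane_id = "lane1") {
  stopifnot(inherits(barcode_map, "barcode_map"))
  bcs <- barcode_map$barcodes
  if (length(bcs) > 1) {
    d <- hamming_matrix(bcs)
    if (min(d[upper.tri(d)]) <= 2L * max_mismatches)
      stop("ambiguous barcode map: two barcodes within ",
           2L * max_mismatches, " mismatches")
  }
  read_fq <- function(f)  # Biostrings warns about its own dropped mcols
    withCallingHandlers(
      Biostrings::readQualityScaledDNAStringSet(f),
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
  r1 <- read_fq(fastq1)
  r2 <- read_fq(fastq2)
  if (length(r1) != length(r2))
    stop("read-1 and read-2 files differ in length")
  n <- length(r1)
  bl <- 6L
  assign <- integer(n) # 0 = unassigned
  if (n > 0) {
    prefmat <- matrix("", nrow = bl, ncol = n)
    pref <- as.character(Biostrings::subseq(r1, 1L, bl))
    for (k in seq_len(bl)) prefmat[k, ] <- substring(pref, k, k)
    best_d <- rep.int(bl + 1L, n)
    for (b in seq_along(bcs)) {
      bchars <- strsplit(bcs[b], "")[[1]]
      mism <- colSums(prefmat != bchars)
      hit <- mism <= max_mismatches & mism < best_d
      assign[hit] <- b
      best_d[hit] <- mism[hit]
    }
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  keep_from <- bl + trim_extra + 1L
  files <- data.frame(sample_id = character(0), R1 = character(0),
                      R2 = character(0), stringsAsFactors = FALSE)
  write_pair <- function(idx, label, trim) {
    f1 <- file.path(outdir, paste0(label, "_R1.fastq"))
    f2 <- file.path(outdir, paste0(label, "_R2.fastq"))
    plain <- function(x)  # drop metadata cols so coercion stays silent
      Biostrings::DNAStringSet(setNames(as.character(x), names(x)))
    a <- r1[idx]
    if (trim && length(idx)) a <- IRanges::narrow(a, start = keep_from)
    Biostrings::writeXStringSet(plain(a), f1, format = "fastq",
                                qualities = Biostrings::BStringSet(
                                  as.character(Biostrings::quality(a))))
    b <- r2[idx]
    Biostrings::writeXStringSet(plain(b), f2, format = "fastq",
                                qualities = Biostrings::BStringSet(
                                  as.character(Biostrings::quality(b))))
    c(f1, f2)
  }
  counts <- integer(length(bcs))
  names(counts) <- barcode_map$sample_ids
  for (b in seq_along(bcs)) {
    idx <- which(assign == b)
    counts[b] <- length(idx)
    ff <- write_pair(idx, barcode_map$sample_ids[b], trim = TRUE)
    files <- rbind(files, data.frame(sample_id = barcode_map$sample_ids[b],
                                     R1 = ff[1], R2 = ff[2],
                                     stringsAsFactors = FALSE))
  }
  un <- which(assign == 0L)
  ff <- write_pair(un, "undetermined", trim = FALSE)
  files <- rbind(files, data.frame(sample_id = "undetermined", R1 = ff[1],
                                   R2 = ff[2], stringsAsFactors = FALSE))
  structure(list(lane_id = lane_id, counts = counts,
                 unassigned = length(un), total = n, files = files),
            class = "lane_counts")
}

#' Construct lane counts directly
#'
#' Per-lane read-pair counts per sample, the unit on which the
#' input-normalised read-proportion statistic is computed.
#'
#' @param counts named non-negative integer vector (sample -> pairs).
#' @param unassigned pairs not attributable to any barcode.
#' @param lane_id lane label (one IP or input pool).
#' @return A `lane_counts` object.
#' @export
lane_counts <- function(counts, unassigned = 0L, lane_id = "lane1") {
  stopifnot(!is.null(names(counts)), all(counts >= 0), unassigned >= 0)
  structure(list(lane_id = lane_id, counts = counts,
                 unassigned = as.integer(unassigned),
                 total = as.integer(sum(counts) + unassigned),
                 files = NULL),
            class = "lane_counts")
}

#' @export
print.lane_counts <- function(x, ...) {
  cat(sprintf("lane_counts '%s': %d pairs (%d unassigned)\n",
              x$lane_id, x$total, x$unassigned))
  print(x$counts)
  invisible(x)
}

#' Input-normalised per-sample read proportions
#'
#' For each sample, the fraction of the IP lane's reads attributed to
#' that sample is divided by the fraction of the chromatin-input lane's
#' reads attributed to it, correcting for unequal pooling of the
#' barcoded chromatin samples. The ratios are also renormalised to sum
#' to one across samples, giving the pooling-corrected share of the IP.
#'
#' @param ip_lane `lane_counts` for the IP pool.
#' @param input_lane `lane_counts` for the chromatin-input pool; every
#'   sample present in `ip_lane` must have a positive input count.
#' @return A `normalized_proportions` object: list with `lane_id`,
#'   `values` (IP fraction / input fraction, per sample) and
#'   `renormalized` (values rescaled to sum to 1).
#' @export
normalized_proportions <- function(ip_lane, input_lane) {
  stopifnot(inherits(ip_lane, "lane_counts"),
            inherits(input_lane, "lane_counts"))
  s <- names(ip_lane$counts)
  missing <- s[!(s %in% names(input_lane$counts)) |
                 input_lane$counts[s] %in% c(NA, 0)]
  if (length(missing))
    stop("sample(s) with zero or missing input count: ",
         paste(missing, collapse = ", "))
  ip_frac <- ip_lane$counts[s] / sum(ip_lane$counts)
  in_frac <- input_lane$counts[s] / sum(input_lane$counts)
  values <- ip_frac / in_frac
  structure(list(lane_id = ip_lane$lane_id, values = values,
                 renormalized = values / sum(values)),
            class = "normalized_proportions")
}

#' Write lane counts / proportions as TSV
#' @param x a `lane_counts` or `normalized_proportions` object.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_lane_tsv <- function(x, path) {
  df <- if (inherits(x, "lane_counts")) {
    rbind(data.frame(lane_id = x$lane_id, sample_id = names(x$counts),
                     count = as.integer(x$counts), stringsAsFactors = FALSE),
          data.frame(lane_id = x$lane_id, sample_id = "unassigned",
                     count = x$unassigned, stringsAsFactors = FALSE))
  } else if (inherits(x, "normalized_proportions")) {
    data.frame(lane_id = x$lane_id, sample_id = names(x$values),
               value = as.numeric(x$values),
               renormalized = as.numeric(x$renormalized),
               stringsAsFactors = FALSE)
  } else stop("unsupported object")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
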