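#' Known histone marks used by the default presets
#' @export
MARKS <- c("H3K4me1", "H3K4me2", "H3K4me3", "H3K14ac", "H3K36me3")

#' Strain preset: the chromatin state the simulator emulates
#'
#' A `strain_preset` bundles everything the generator needs to emulate
#' one yeast strain: which marks the strain lacks entirely (e.g. no
#' H3K4 methylation in a Set1 deletion, no H3K36me3 in a Set2 deletion),
#' how each mark is laid out along gene-relative nucleosome indices,
#' nucleosome positioning geometry (repeat length, nucleosome-depleted
#' region upstream of the TSS, positional jitter), the MNase
#' fragment-length distribution, and the fraction of genes that acquire
#' internal (cryptic) transcription initiation.
#'
#' Nucleosome indices are gene-relative: +1 is the first nucleosome
#' downstream of the TSS, -1 the first upstream of the NDR.
#'
#' @param strain_id label, e.g. `"WT"` or `"set1d"`.
#' @param absent_marks character vector of marks the strain cannot
#'   carry; their layout probabilities are forced to 0.
#' @param mark_layout named list, one element per mark, each a
#'   data.frame with columns `index` (nucleosome index) and `prob`
#'   (probability in \[0,1\] that a nucleosome at that index carries the
#'   mark); unlisted indices have probability 0. Defaults to
#'   [default_mark_layout()].
#' @param nucleosome_repeat nucleosome repeat length in bp (> 146).
#' @param ndr_center_offset bp upstream of the TSS at which the
#'   nucleosome-depleted region is centred (positive number).
#' @param ndr_width width of the NDR in bp (> 0).
#' @param edge_to_dyad distance in bp from an NDR edge to the first
#'   flanking dyad (half a nucleosome plus linker). The +1 dyad sits at
#'   `-ndr_center_offset + ndr_width/2 + edge_to_dyad` and the -1 dyad
#'   mirrored across the NDR, so widening the NDR widens the recovered
#'   trough by the same amount. Defaults (centre 100 bp upstream, width
#'   140, pad 105) put the +1 dyad at +75 and the -1 dyad at -275.
#' @param plus_one_offset optional explicit dyad position of the +1
#'   nucleosome (bp downstream of the TSS); `NULL` (default) derives it
#'   from the NDR geometry as above.
#' @param jitter_sd per-nucleosome positional jitter sd in bp.
#' @param fragment_length_mean,fragment_length_sd mono-nucleosomal
#'   fragment length distribution (normal, truncated to
#'   \[100, 250\] bp at sampling time).
#' @param cryptic_gene_fraction proportion of genes gaining internal
#'   initiation in this strain.
#' @param cryptic_length_weighted if `TRUE` (default) cryptic status is
#'   assigned with probability proportional to gene length, reproducing
#'   the long-gene bias of cryptic genes.
#' @param upstream_span bp upstream of the TSS over which the phased
#'   upstream nucleosome array is generated.
#' @return An object of class `strain_preset`.
#' @export
strain_preset <- function(strain_id,
                          absent_marks = character(),
                          mark_layout = default_mark_layout(),
                          nucleosome_repeat = 150L,
                          ndr_center_offset = 100L,
                          ndr_width = 140L,
                          edge_to_dyad = 105L,
                          plus_one_offset = NULL,
                          jitter_sd = 20,
                          fragment_length_mean = 150,
                          fragment_length_sd = 10,
                          cryptic_gene_fraction = 0,
                          cryptic_length_weighted = TRUE,
                          upstream_span = 1000L) {
  stopifnot(nucleosome_repeat > 146, ndr_width > 0, ndr_center_offset >= 0,
            jitter_sd >= 0, cryptic_gene_fraction >= 0,
            cryptic_gene_fraction <= 1)
  if (!all(vapply(mark_layout, function(l)
    all(l$prob >= 0 & l$prob <= 1), logical(1))))
    stop("mark layout probabilities must lie in [0, 1]")
  unknown <- setdiff(absent_marks, names(mark_layout))
  if (length(unknown))
    mark_layout[unknown] <- list(data.frame(index = integer(), prob = numeric()))
  for (m in absent_marks)
    mark_layout[[m]]$prob <- rep(0, nrow(mark_layout[[m]]))
  structure(list(strain_id = strain_id, absent_marks = absent_marks,
                 mark_layout = mark_layout,
                 nucleosome_repeat = as.integer(nucleosome_repeat),
                 ndr_center_offset = as.integer(ndr_center_offset),
                 ndr_width = as.integer(ndr_width),
                 edge_to_dyad = as.integer(edge_to_dyad),
                 plus_one_offset = if (!is.null(plus_one_offset))
                   as.integer(plus_one_offset),
                 jitter_sd = jitter_sd,
                 fragment_length_mean = fragment_length_mean,
                 fragment_length_sd = fragment_length_sd,
                 cryptic_gene_fraction = cryptic_gene_fraction,
                 cryptic_length_weighted = cryptic_length_weighted,
                 upstream_span = as.integer(upstream_span)),
            class = "strain_preset")
}

#' Default gene-relative mark layout
#'
#' Encodes the canonical 5'-to-3' ordering of marks along yeast genes:
#' H3K4me3 and H3K14ac concentrated on the first nucleosomes after the
#' TSS (within roughly +1..+500 bp at a 150 bp repeat), H3K4me2 peaking
#' around +500 bp, H3K4me1 around +600 bp, and H3K36me3 on 3'
#' gene-body nucleosomes. Probabilities are presets for the simulator,
#' not measured quantities.
#'
#' @return Named list of data.frames with columns `index`, `prob`.
#' @export
default_mark_layout <- function() {
  list(
    H3K4me3 = data.frame(index = c(1L, 2L, 3L, 4L),
                         prob = c(0.90, 0.80, 0.50, 0.15)),
    H3K14ac = data.frame(index = c(-1L, 1L, 2L, 3L),
                         prob = c(0.30, 0.85, 0.70, 0.35)),
    H3K4me2 = data.frame(index = c(2L, 3L, 4L, 5L),
                         prob = c(0.35, 0.70, 0.70, 0.40)),
    H3K4me1 = data.frame(index = c(3L, 4L, 5L, 6L),
                         prob = c(0.30, 0.60, 0.60, 0.35)),
    H3K36me3 = data.frame(index = 4:12, prob = rep(0.80, 9))
  )
}

#' Bundled strain presets
#'
#' Convenience presets for the wild type and the chromatin-modifier
#' deletion strains the workflow is designed around: `set1d` lacks all
#' H3K4 methylation, `set2d` lacks H3K36me3 and acquires cryptic
#' internal initiation in a subset of (preferentially long) genes and a
#' gene-body spread of H3K14ac, `eaf3d` and `rco1d` show gene-body
#' H3K14ac; `eaf3d` and `set1d` are more MNase-sensitive (shorter
#' fragments, wider NDR).
#'
#' @param strain one of `"WT"`, `"set1d"`, `"set2d"`, `"eaf3d"`,
#'   `"rco1d"`.
#' @param ... overrides passed on to [strain_preset()].
#' @return A [strain_preset()].
#' @export
preset_strain <- function(strain = c("WT", "set1d", "set2d", "eaf3d", "rco1d"),
                          ...) {
  strain <- match.arg(strain)
  body_ac <- function(l) { # spread H3K14ac through the gene body
    l$H3K14ac <- data.frame(index = c(-1L, 1:12),
                            prob = c(0.30, rep(0.70, 12)))
    l
  }
  args <- switch(strain,
    WT = list(strain_id = "WT"),
    set1d = list(strain_id = "set1d",
                 absent_marks = c("H3K4me1", "H3K4me2", "H3K4me3"),
                 fragment_length_mean = 145, ndr_width = 190L),
    set2d = list(strain_id = "set2d", absent_marks = "H3K36me3",
                 mark_layout = body_ac(default_mark_layout()),
                 cryptic_gene_fraction = 0.1),
    eaf3d = list(strain_id = "eaf3d",
                 mark_layout = body_ac(default_mark_layout()),
                 fragment_length_mean = 145, ndr_width = 190L),
    rco1d = list(strain_id = "rco1d",
                 mark_layout = body_ac(default_mark_layout())))
  do.call(strain_preset, modifyList(args, list(...)))
}

#' Barcode-to-sample map
#'
#' Inline 6-mer barcodes identifying the biological sample each read
#' pair derives from. Barcodes must be unique and separated by at least
#' `min_pairwise_hamming` mismatches so that demultiplexing with up to
#' `floor((min_pairwise_hamming - 1) / 2)` mismatches is unambiguous.
#'
#' @param barcodes character vector of 6-mer DNA barcodes.
#' @param sample_ids character vector of sample labels, same length.
#' @param min_pairwise_hamming required minimum pairwise Hamming
#'   distance between barcodes (default 2).
#' @return An object of class `barcode_map`.
#' @export
barcode_map <- function(barcodes, sample_ids, min_pairwise_hamming = 2L) {
  barcodes <- toupper(as.character(barcodes))
  sample_ids <- as.character(sample_ids)
  stopifnot(length(barcodes) == length(sample_ids))
  if (!all(nchar(barcodes) == 6L))
    stop("all barcodes must have length 6")
  if (!all(grepl("^[ACGT]+$", barcodes)))
    stop("barcodes must use alphabet {A,C,G,T}")
  if (anyDuplicated(barcodes)) stop("barcodes must be unique")
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique")
  if (length(barcodes) > 1) {
    d <- hamming_matrix(barcodes)
    if (min(d[upper.tri(d)]) < min_pairwise_hamming)
      stop("barcode pair closer than min_pairwise_hamming: ",
           min(d[upper.tri(d)]))
  }
  structure(list(barcodes = barcodes, sample_ids = sample_ids,
                 min_pairwise_hamming = as.integer(min_pairwise_hamming)),
            class = "barcode_map")
}

hamming_matrix <- function(codes) {
  chars <- do.call(rbind, strsplit(codes, ""))
  n <- length(codes)
  d <- matrix(0L, n, n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      d[i, j] <- sum(chars[i, ] != chars[j, ])
  d
}

#' Generate well-separated 6-mer barcodes
#'
#' Greedy selection of random 6-mers at pairwise Hamming distance at
#' least `min_dist`, for building synthetic [barcode_map()]s.
#'
#' @param n number of barcodes.
#' @param sample_ids optional labels (default `S1..Sn`).
#' @param min_dist minimum pairwise Hamming distance (default 3).
#' @param seed integer seed.
#' @return A [barcode_map()].
#' @export
random_barcode_map <- function(n, sample_ids = sprintf("S%02d", seq_len(n)),
                               min_dist = 3L, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    chosen <- character(0)
    tries <- 0
    while (length(chosen) < n) {
      cand <- paste(sample(c("A", "C", "G", "T"), 6, replace = TRUE),
                    collapse = "")
      ok <- all(vapply(chosen, function(b)
        sum(strsplit(b, "")[[1]] != strsplit(cand, "")[[1]]) >= min_dist,
        logical(1)))
      if (ok) chosen <- c(chosen, cand)
      tries <- tries + 1
      if (tries > 100000) stop("could not find ", n, " barcodes at distance ",
                               min_dist)
    }
    barcode_map(chosen, sample_ids, min_pairwise_hamming = min_dist)
  })
}

#' Read / write a barcode map as TSV
#'
#' Two-column TSV (`sample_id`, `barcode`) with header.
#'
#' @param path file path.
#' @param map a [barcode_map()] (for writing).
#' @param min_pairwise_hamming passed to [barcode_map()] when reading.
#' @return [read_barcode_map()] returns a [barcode_map()];
#'   [write_barcode_map()] returns `path` invisibly.
#' @export
read_barcode_map <- function(path, min_pairwise_hamming = 2L) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  barcode_map(df$barcode, df$sample_id, min_pairwise_hamming)
}

#' @rdname read_barcode_map
#' @export
write_barcode_map <- function(map, path) {
  write.table(data.frame(sample_id = map$sample_ids, barcode = map$barcodes),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
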