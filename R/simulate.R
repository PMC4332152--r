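#' Place a phased nucleosome array with mark labels (ground truth)
#'
#' For every gene a phased array of nucleosome dyads is laid down in
#' TSS-relative coordinates: the +1 nucleosome `edge_to_dyad` bp
#' downstream of the NDR's downstream edge (at +75 with the default
#' geometry), further downstream dyads every `nucleosome_repeat` bp
#' until the end of the gene body, and an upstream array mirrored
#' across the nucleosome-depleted region (NDR) so that the occupancy
#' minimum falls `ndr_center_offset` bp upstream of the TSS and the
#' trough widens with `ndr_width`. No dyad is placed inside the NDR
#' interval. Each dyad is
#' jittered by a Gaussian of sd `jitter_sd` and draws its mark labels
#' per the preset's layout; marks in `absent_marks` are never carried.
#'
#' Genes acquiring internal (cryptic) initiation are also drawn here,
#' with probability proportional to gene length when the preset says so,
#' and each receives an internal initiation position at least 200 bp
#' into the gene body.
#'
#' @param genome a [genome_model()].
#' @param preset a [strain_preset()].
#' @param seed integer seed.
#' @param sample_id label for this biological sample (defaults to the
#'   preset's strain id); stored with every truth nucleosome.
#' @return A `truth_table`: list with `nucleosomes` (data.frame with
#'   chromosome, dyad, gene_id, nuc_index, sample_id and one logical
#'   column per mark) and `genes` (gene_id, sample_id, cryptic,
#'   internal_tss_position in gene-relative bp or NA). The preset is
#'   attached as attribute `"preset"`.
#' @export
place_nucleosomes <- function(genome, preset, seed = 1L,
                              sample_id = preset$strain_id) {
  stopifnot(inherits(genome, "genome_model"), inherits(preset, "strain_preset"))
  gb <- gene_body_bounds(genome)
  clen <- chrom_length(genome, gb$chromosome)
  rep_len_bp <- preset$nucleosome_repeat
  ndr_c <- -preset$ndr_center_offset
  plus_one <- if (!is.null(preset$plus_one_offset)) preset$plus_one_offset else
    ndr_c + preset$ndr_width %/% 2L + preset$edge_to_dyad
  minus_one <- 2L * ndr_c - plus_one
  withr::with_seed(as.integer(seed), {
    per_gene <- vector("list", nrow(gb))
    for (i in seq_len(nrow(gb))) {
      down <- seq(plus_one, max(plus_one, gb$length[i]), by = rep_len_bp)
      up <- seq(minus_one, -(preset$upstream_span + rep_len_bp), by = -rep_len_bp)
      offs <- c(rev(up), down)
      idx <- c(rev(seq_along(up)) * -1L, seq_along(down))
      if (preset$jitter_sd > 0)
        offs <- offs + round(rnorm(length(offs), 0, preset$jitter_sd))
      gpos <- if (gb$strand[i] == "+") gb$tss[i] + offs else gb$tss[i] - offs
      keep <- gpos >= 0L & gpos < clen[i]
      per_gene[[i]] <- data.frame(
        chromosome = gb$chromosome[i], dyad = as.integer(gpos[keep]),
        gene_id = gb$gene_id[i], nuc_index = idx[keep],
        sample_id = sample_id, stringsAsFactors = FALSE)
    }
    nuc <- do.call(rbind, per_gene)
    for (m in names(preset$mark_layout)) {
      lay <- preset$mark_layout[[m]]
      p <- lay$prob[match(nuc$nuc_index, lay$index)]
      p[is.na(p)] <- 0
      nuc[[m]] <- rbinom(nrow(nuc), 1L, p) == 1L
    }
    # cryptic-gene assignment
    n_cryptic <- round(preset$cryptic_gene_fraction * nrow(gb))
    cryptic <- rep(FALSE, nrow(gb))
    if (n_cryptic > 0) {
      w <- if (preset$cryptic_length_weighted) gb$length else rep(1, nrow(gb))
      cryptic[sample.int(nrow(gb), n_cryptic, prob = w)] <- TRUE
    }
    internal <- rep(NA_integer_, nrow(gb))
    if (any(cryptic)) {
      lo <- pmax(250L, 200L)
      hi <- pmax(lo + 50L, gb$length[cryptic] - 100L)
      internal[cryptic] <- as.integer(round(runif(sum(cryptic), lo, hi)))
    }
    genes <- data.frame(gene_id = gb$gene_id, sample_id = sample_id,
                        cryptic = cryptic, internal_tss_position = internal,
                        gene_length = gb$length, stringsAsFactors = FALSE)
    structure(list(nucleosomes = nuc, genes = genes),
              class = "truth_table", preset = preset)
  })
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  x
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

#' Simulate a pooled multiplexed IP (or input) sequencing lane
#'
#' Emulates the pooled immuno-precipitation of barcoded chromatin:
#' aliquots of several barcoded samples are combined into one pool,
#' subjected to one IP, and sequenced as one lane. Each emitted fragment
#' is drawn around one ground-truth nucleosome dyad with a
#' mono-nucleosomal length from the sample preset's truncated-normal
#' distribution. For an IP lane, nucleosomes carrying `ip_mark` are
#' sampled with weight `enrichment` and unmarked ones with weight
#' `background_rate`; for `ip_mark = "input"` all nucleosomes are
#' sampled uniformly. PCR duplication adds geometric extra identical
#' copies at the stated rate. Optionally, paired-end FASTQ is emitted
#' with the sample's 6-mer barcode prepended to read 1.
#'
#' @param truths named list of `truth_table`s, one per pooled sample;
#'   names are the sample ids and must match `barcode_map$sample_ids`.
#' @param barcode_map a [barcode_map()] covering every pooled sample.
#' @param ip_mark histone mark to pull down, or `"input"`.
#' @param enrichment sampling weight of marked nucleosomes (>= 1).
#' @param background_rate sampling weight of unmarked nucleosomes.
#' @param n_fragments number of fragment originals to emit (before PCR
#'   duplication).
#' @param pcr_duplication_rate geometric duplication parameter in
#'   \[0, 1); the expected number of extra copies per original is
#'   `rate / (1 - rate)`.
#' @param seed integer seed.
#' @param fastq_prefix if non-NULL, write `<prefix>_R1.fastq` and
#'   `<prefix>_R2.fastq`.
#' @param read_length read length for FASTQ emission.
#' @param error_rate uniform per-base substitution error rate applied
#'   to emitted reads (default 0: error-free).
#' @return A `lane_simulation`: list with `fragments` (data.frame:
#'   chromosome, start, end, sample_id, copies, gene_id, nuc_index,
#'   marked, fragment_id; 0-based half-open coordinates), `lane_id`,
#'   `ip_mark`, and `fastq` (paths or NULL).
#' @export
simulate_pool <- function(truths, barcode_map, ip_mark = "input",
                          enrichment = 20, background_rate = 0.05,
                          n_fragments = 10000L, pcr_duplication_rate = 0,
                          seed = 1L, fastq_prefix = NULL, read_length = 50L,
                          error_rate = 0) {
  stopifnot(is.list(truths), length(truths) >= 1,
            inherits(barcode_map, "barcode_map"))
  if (is.null(names(truths)) || any(names(truths) == ""))
    stop("truths must be a named list (names are sample ids)")
  if (!all(names(truths) %in% barcode_map$sample_ids))
    stop("every pooled sample needs a barcode")
  if (ip_mark != "input" && enrichment < 1)
    stop("enrichment must be >= 1")
  pool <- do.call(rbind, lapply(names(truths), function(s) {
    nuc <- truths[[s]]$nucleosomes
    nuc$sample_id <- s
    pr <- attr(truths[[s]], "preset")
    nuc$frag_mean <- pr$fragment_length_mean
    nuc$frag_sd <- pr$fragment_length_sd
    if (ip_mark == "input") {
      nuc$marked <- NA
    } else {
      if (!ip_mark %in% names(pr$mark_layout))
        stop("ip_mark unknown to preset of sample ", s, ": ", ip_mark)
      nuc$marked <- nuc[[ip_mark]]
    }
    nuc[, c("chromosome", "dyad", "gene_id", "nuc_index", "sample_id",
            "marked", "frag_mean", "frag_sd")]
  }))
  if (nrow(pool) == 0) stop("empty pool: no truth nucleosomes")
  w <- if (ip_mark == "input") rep(1, nrow(pool)) else
    ifelse(pool$marked, enrichment, background_rate)
  if (sum(w) <= 0)
    stop("empty pool: all sampling weights are zero")
  withr::with_seed(as.integer(seed), {
    pick <- sample.int(nrow(pool), n_fragments, replace = TRUE, prob = w)
    sel <- pool[pick, ]
    len <- as.integer(round(rtrunc_norm(n_fragments, sel$frag_mean,
                                        sel$frag_sd, 100, 250)))
    start <- as.integer(sel$dyad - len %/% 2L)
    start <- pmax(start, 0L)
    end <- start + len
    extra <- if (pcr_duplication_rate > 0)
      rgeom(n_fragments, prob = 1 - pcr_duplication_rate) else
      rep(0L, n_fragments)
    frags <- data.frame(
      chromosome = sel$chromosome, start = start, end = end,
      sample_id = sel$sample_id, copies = 1L + extra,
      gene_id = sel$gene_id, nuc_index = sel$nuc_index,
      marked = sel$marked,
      fragment_id = sprintf("frag%07d", seq_len(n_fragments)),
      stringsAsFactors = FALSE)
    fastq <- NULL
    if (!is.null(fastq_prefix))
      fastq <- write_pool_fastq(frags, barcode_map, fastq_prefix,
                                read_length, error_rate)
    structure(list(fragments = frags,
                   lane_id = if (ip_mark == "input") "input" else ip_mark,
                   ip_mark = ip_mark, fastq = fastq),
              class = "lane_simulation")
  })
}

# Emit one read pair per fragment copy; read 1 carries the 6-mer barcode
# as an inline prefix. Sequence content beyond the barcode is random
# (no sequence-level realism); read names carry the fragment id so
# provenance can be audited after demultiplexing.
write_pool_fastq <- function(frags, barcode_map, prefix, read_length,
                             error_rate) {
  reps <- rep(seq_len(nrow(frags)), frags$copies)
  bcs <- barcode_map$barcodes[match(frags$sample_id[reps],
                                    barcode_map$sample_ids)]
  body1 <- random_dna(length(reps), read_length)
  body2 <- random_dna(length(reps), read_length)
  s1 <- paste0(bcs, body1)
  if (error_rate > 0) {
    s1 <- apply_sequencing_errors(s1, error_rate)
    body2 <- apply_sequencing_errors(body2, error_rate)
  }
  copy_no <- sequence(frags$copies)
  nm <- sprintf("%s:%d", frags$fragment_id[reps], copy_no)
  r1 <- Biostrings::DNAStringSet(setNames(s1, nm))
  r2 <- Biostrings::DNAStringSet(setNames(body2, nm))
  q1 <- Biostrings::BStringSet(strrep("I", nchar(s1)))
  q2 <- Biostrings::BStringSet(strrep("I", nchar(body2)))
  f1 <- paste0(prefix, "_R1.fastq")
  f2 <- paste0(prefix, "_R2.fastq")
  Biostrings::writeXStringSet(r1, f1, format = "fastq", qualities = q1)
  Biostrings::writeXStringSet(r2, f2, format = "fastq", qualities = q2)
  c(R1 = f1, R2 = f2)
}

apply_sequencing_errors <- function(seqs, rate) {
  vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1]]
    hit <- runif(length(ch)) < rate
    if (any(hit)) {
      subs <- vapply(ch[hit], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
      ch[hit] <- subs
    }
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate CAGE-like 5'-end tag data
#'
#' Every gene emits Poisson(`tags_per_gene`) 5'-end tags. Tags start at
#' the annotated TSS with a small Gaussian jitter, except for a
#' background fraction (`baseline_internal_fraction`, all genes) placed
#' uniformly inside the gene body, emulating pervasive low-level
#' internal initiation, and — for genes flagged cryptic in the truth
#' table — an additional `internal_fraction_when_cryptic` of tags at the
#' gene's internal initiation position.
#'
#' @param genome a [genome_model()].
#' @param truth a `truth_table` from [place_nucleosomes()] (carries the
#'   cryptic labels).
#' @param tags_per_gene expected tag count per gene.
#' @param internal_fraction_when_cryptic extra fraction of tags emitted
#'   at the internal initiation position of cryptic genes.
#' @param seed integer seed.
#' @param baseline_internal_fraction background fraction of tags
#'   scattered uniformly in the body of every gene.
#' @param tss_jitter_sd Gaussian jitter of tag 5' positions in bp.
#' @param sample_id label stored with each tag.
#' @return data.frame of 5'-end tag records: chromosome,
#'   five_prime_position (0-based), strand, n_alignments,
#'   softclip_5prime, softclip_total_fraction, sample_id.
#' @export
simulate_cage_tags <- function(genome, truth, tags_per_gene = 200,
                               internal_fraction_when_cryptic = 0.15,
                               seed = 1L, baseline_internal_fraction = 0.05,
                               tss_jitter_sd = 10,
                               sample_id = truth$genes$sample_id[1]) {
  stopifnot(inherits(genome, "genome_model"), inherits(truth, "truth_table"))
  gb <- gene_body_bounds(genome)
  tg <- truth$genes[match(gb$gene_id, truth$genes$gene_id), ]
  withr::with_seed(as.integer(seed), {
    out <- vector("list", nrow(gb))
    for (i in seq_len(nrow(gb))) {
      n <- rpois(1, tags_per_gene)
      if (n == 0) next
      p_int <- baseline_internal_fraction +
        if (isTRUE(tg$cryptic[i])) internal_fraction_when_cryptic else 0
      u <- runif(n)
      cryptic_tag <- isTRUE(tg$cryptic[i]) &
        u < internal_fraction_when_cryptic
      bg_tag <- !cryptic_tag & u < p_int
      off <- integer(n)
      off[!cryptic_tag & !bg_tag] <-
        round(rnorm(sum(!cryptic_tag & !bg_tag), 0, tss_jitter_sd))
      off[bg_tag] <- as.integer(floor(runif(sum(bg_tag), 0, gb$length[i])))
      if (any(cryptic_tag))
        off[cryptic_tag] <- tg$internal_tss_position[i] +
          round(rnorm(sum(cryptic_tag), 0, tss_jitter_sd))
      gpos <- if (gb$strand[i] == "+") gb$tss[i] + off else gb$tss[i] - off
      gpos <- pmax(0L, pmin(as.integer(gpos),
                            chrom_length(genome, gb$chromosome[i]) - 1L))
      out[[i]] <- data.frame(
        chromosome = gb$chromosome[i], five_prime_position = gpos,
        strand = gb$strand[i], n_alignments = 1L, softclip_5prime = 0L,
        softclip_total_fraction = 0, sample_id = sample_id,
        stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
}

#' Write / read a fragment table (BED-like TSV)
#'
#' Columns: chromosome, start, end (0-based half-open), sample_id,
#' copies; extra provenance columns are kept if present.
#'
#' @param fragments fragment data.frame.
#' @param path file path.
#' @return `write_fragments()` returns `path` invisibly;
#'   `read_fragments()` returns a data.frame.
#' @export
write_fragments <- function(fragments, path) {
  write.table(fragments, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fragments
#' @export
read_fragments <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write truth tables as TSV
#' @param truth a `truth_table`.
#' @param prefix output path prefix; writes `<prefix>_nucleosomes.tsv`
#'   and `<prefix>_genes.tsv`.
#' @return The two paths, invisibly.
#' @export
write_truth_table <- function(truth, prefix) {
  p1 <- paste0(prefix, "_nucleosomes.tsv")
  p2 <- paste0(prefix, "_genes.tsv")
  write.table(truth$nucleosomes, p1, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(truth$genes, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(nucleosomes = p1, genes = p2))
}
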