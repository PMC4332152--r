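# Shared fixtures, built in code at test time.

# tiny deterministic genome: one chromosome, two genes on opposite strands
tiny_genome <- function() {
  genome_model(
    chromosomes = data.frame(name = "chrT", length = 20000L),
    genes = data.frame(gene_id = c("gA", "gB"),
                       chromosome = "chrT",
                       strand = c("+", "-"),
                       tss = c(3000L, 15000L),
                       length = c(2000L, 2000L)))
}

# the stated wild-type input experiment: 200 genes, default WT preset
# (jitter 20 bp, fragment sd 10 bp), input pool, filtered midpoints
wt_input_profile <- function(seed = 1L, n_genes = 200L,
                             n_fragments = 200000L) {
  g <- build_genome(2, n_genes, 1500, seed = seed)
  tr <- place_nucleosomes(g, preset_strain("WT"), seed = seed + 1L,
                          sample_id = "WT_rep1")
  bm <- random_barcode_map(1, "WT_rep1", seed = 3)
  pool <- simulate_pool(list(WT_rep1 = tr), bm, ip_mark = "input",
                        n_fragments = n_fragments,
                        pcr_duplication_rate = 0.05, seed = seed + 2L)
  fr <- filter_fragments(pool$fragments, filter_config(), is_input = TRUE)
  fr <- deduplicate(fr, 2L)
  list(genome = g, truth = tr,
       profile = tss_profile(build_track(midpoints(fr), g), g))
}

# minimal SAM text fixture: FR pair, RF pair, pair with a secondary
# alignment, low-MAPQ pair; 1-based SAM coordinates, 10 bp reads
write_test_sam <- function(path) {
  lines <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chrT\tLN:20000",
    # FR pair: mate1 + at 101, mate2 - at 241 (fragment [100, 250))
    "fr1\t99\tchrT\t101\t42\t10M\t=\t241\t150\tACGTACGTAC\tIIIIIIIIII",
    "fr1\t147\tchrT\t241\t42\t10M\t=\t101\t-150\tACGTACGTAC\tIIIIIIIIII",
    # RF (outward-facing) pair
    "rf1\t83\tchrT\t501\t42\t10M\t=\t641\t150\tACGTACGTAC\tIIIIIIIIII",
    "rf1\t163\tchrT\t641\t42\t10M\t=\t501\t-150\tACGTACGTAC\tIIIIIIIIII",
    # pair with a secondary alignment record for mate 1
    "sec1\t99\tchrT\t1001\t30\t10M\t=\t1141\t150\tACGTACGTAC\tIIIIIIIIII",
    "sec1\t147\tchrT\t1141\t30\t10M\t=\t1001\t-150\tACGTACGTAC\tIIIIIIIIII",
    "sec1\t355\tchrT\t5001\t0\t10M\t=\t5141\t150\tACGTACGTAC\tIIIIIIIIII",
    # low-MAPQ FR pair
    "lo1\t99\tchrT\t2001\t5\t10M\t=\t2141\t150\tACGTACGTAC\tIIIIIIIIII",
    "lo1\t147\tchrT\t2141\t5\t10M\t=\t2001\t-150\tACGTACGTAC\tIIIIIIIIII")
  writeLines(lines, path)
  path
}

# hand-built tss_profile for locator unit tests
profile_from_occupancy <- function(occ, window = c(-1000L, 1500L),
                                   total = 1000) {
  structure(list(window = as.integer(window),
                 positions = seq.int(window[1], window[2]),
                 counts = occ * total, occupancy = occ,
                 n_genes = 1L, total_midpoints = total, truncated = 0L),
            class = "tss_profile")
}
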