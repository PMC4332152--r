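#' Multiplex experiment design accounting
#'
#' A multiplexed design with `S` strains, `R` replicates per strain and
#' `M` IP marks (plus, optionally, one input assay) produces
#' `S * R` biological samples, `M` IP assays, and
#' `S * R * (M + include_input)` equivalent single-sample ChIP-seq
#' datasets — each (sample, assay) pair is one dataset.
#'
#' @param strains character vector (or count) of strains.
#' @param replicates_per_strain replicates per strain (>= 1).
#' @param marks character vector (or count) of IP targets.
#' @param include_input is a chromatin-input lane included?
#' @return An `experiment_design` object.
#' @export
experiment_design <- function(strains, replicates_per_strain, marks,
                              include_input = TRUE) {
  n_strains <- if (is.numeric(strains)) as.integer(strains) else length(strains)
  n_marks <- if (is.numeric(marks)) as.integer(marks) else length(marks)
  stopifnot(n_strains >= 1, replicates_per_strain >= 1, n_marks >= 1)
  structure(list(strains = strains,
                 replicates_per_strain = as.integer(replicates_per_strain),
                 marks = marks, include_input = isTRUE(include_input),
                 n_strains = n_strains, n_marks = n_marks),
            class = "experiment_design")
}

#' @rdname experiment_design
#' @param design an `experiment_design`.
#' @return [design_accounting()] returns a named integer vector with
#'   `n_samples`, `n_ip_assays` and `n_equivalent_datasets`.
#' @export
design_accounting <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  n_samples <- design$n_strains * design$replicates_per_strain
  n_assays <- design$n_marks
  c(n_samples = n_samples,
    n_ip_assays = n_assays,
    n_equivalent_datasets = n_samples * (n_assays + design$include_input))
}

#' Default pipeline configuration
#'
#' A single declarative document driving [run_pipeline()]. Unknown keys
#' are rejected; thresholds are validated before any stage runs. The
#' single `seed` expands deterministically into per-stage,
#' per-replicate seeds.
#'
#' @param ... overrides of the default fields (see the returned list).
#' @return A validated `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    n_chromosomes = 1L,
    n_genes = 60L,
    gene_length_mean = 1500,
    strains = c("WT", "set1d"),
    replicates = 2L,
    ip_marks = "H3K4me3",
    n_fragments = 20000L,
    enrichment = 20,
    background_rate = 0.05,
    pcr_duplication_rate = 0.05,
    emit_fastq = TRUE,
    max_fragment = 220L,
    min_fragment = 130L,
    input_min_fragment = 100L,
    duplicate_cap = 2L,
    window = c(-1000L, 1500L),
    lfc_threshold = 0.05,
    lfdr_threshold = 0.2,
    diff_mark = "H3K4me3",
    condition_a = "WT",
    condition_b = "set1d",
    cage_tags_per_gene = 0,   # 0 disables the cryptic stage
    cage_internal_fraction = 0.15,
    cage_baseline_fraction = 0.05,
    cage_padj_threshold = 0.1)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- modifyList(cfg, over)
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  if (cfg$lfdr_threshold <= 0 || cfg$lfc_threshold <= 0)
    stop("config error: thresholds must be positive")
  if (cfg$replicates < 1 || cfg$n_genes < 1 || cfg$n_fragments < 1)
    stop("config error: counts must be >= 1")
  if (length(cfg$strains) < 1) stop("config error: need at least one strain")
  if (!all(c(cfg$condition_a, cfg$condition_b) %in% cfg$strains))
    stop("config error: diff conditions must be simulated strains")
  invisible(cfg)
}

#' Load a pipeline configuration from a JSON file
#' @param path JSON file with (a subset of) the [run_config()] fields.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  do.call(run_config, jsonlite::fromJSON(path, simplifyVector = TRUE))
}

derive_seed <- function(seed, stage, k = 0L) {
  h <- sum(utf8ToInt(stage)) %% 1000L
  as.integer((as.double(seed) * 7919 + h * 104729 + k * 15485863) %% 2147483647)
}

#' Run the full pipeline from a config
#'
#' Executes the stages in order — simulate, demultiplex (when FASTQ is
#' emitted), fragment filtering, occupancy profiles, differential
#' occupancy, cryptic-initiation calling — writing every inter-stage
#' product as TSV under `outdir` plus a JSON manifest recording seeds,
#' parameters and output files. Re-running with the same config
#' reproduces byte-identical TSV outputs.
#'
#' @param cfg a [run_config()].
#' @param outdir output directory (created if needed).
#' @return Invisibly, a list with the main in-memory results and the
#'   manifest path.
#' @export
run_pipeline <- function(cfg = run_config(), outdir = tempfile("nucleomux")) {
  validate_run_config(cfg)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(...) message("[nucleomux] ", ...)
  manifest <- list(package_version = as.character(utils::packageVersion("nucleomux")),
                   config = cfg, files = list())
  add_file <- function(stage, path) {
    manifest$files[[length(manifest$files) + 1L]] <<-
      list(stage = stage, path = basename(path))
    path
  }

  # --- simulate -----------------------------------------------------------
  log_stage("stage simulate")
  genome <- build_genome(cfg$n_chromosomes, cfg$n_genes, cfg$gene_length_mean,
                         seed = derive_seed(cfg$seed, "genome"))
  sample_ids <- as.vector(outer(cfg$strains, seq_len(cfg$replicates),
                                function(s, r) sprintf("%s_rep%d", s, r)))
  truths <- list()
  k <- 0L
  for (s in cfg$strains) for (r in seq_len(cfg$replicates)) {
    k <- k + 1L
    sid <- sprintf("%s_rep%d", s, r)
    truths[[sid]] <- place_nucleosomes(
      genome, preset_strain(s), seed = derive_seed(cfg$seed, "truth", k),
      sample_id = sid)
  }
  bmap <- random_barcode_map(length(sample_ids), sample_ids,
                             seed = derive_seed(cfg$seed, "barcodes"))
  write_barcode_map(bmap, add_file("simulate", file.path(outdir, "barcodes.tsv")))
  lanes <- list()
  for (lane in c(cfg$ip_marks, "input")) {
    pref <- if (isTRUE(cfg$emit_fastq))
      file.path(outdir, paste0("pool_", lane)) else NULL
    lanes[[lane]] <- simulate_pool(
      truths, bmap, ip_mark = lane, enrichment = cfg$enrichment,
      background_rate = cfg$background_rate, n_fragments = cfg$n_fragments,
      pcr_duplication_rate = cfg$pcr_duplication_rate,
      seed = derive_seed(cfg$seed, paste0("pool_", lane)),
      fastq_prefix = pref)
    write_fragments(lanes[[lane]]$fragments,
                    add_file("simulate",
                             file.path(outdir, paste0("fragments_", lane, ".tsv"))))
  }

  # --- demultiplex --------------------------------------------------------
  demux <- NULL
  if (isTRUE(cfg$emit_fastq)) {
    log_stage("stage demux")
    demux <- lapply(names(lanes), function(lane) {
      fq <- lanes[[lane]]$fastq
      lc <- demultiplex_pairs(fq[["R1"]], fq[["R2"]], bmap,
                              outdir = file.path(outdir, paste0("demux_", lane)),
                              lane_id = lane)
      write_lane_tsv(lc, add_file("demux",
                                  file.path(outdir, paste0("lane_counts_", lane, ".tsv"))))
      lc
    })
    names(demux) <- names(lanes)
    for (lane in cfg$ip_marks) {
      np <- normalized_proportions(demux[[lane]], demux[["input"]])
      write_lane_tsv(np, add_file("demux",
                                  file.path(outdir, paste0("proportions_", lane, ".tsv"))))
    }
  }

  # --- fragments ----------------------------------------------------------
  log_stage("stage fragments")
  fcfg <- filter_config(cfg$max_fragment, cfg$min_fragment,
                        cfg$input_min_fragment, cfg$duplicate_cap)
  mids <- list()   # mids[[lane]][[sample]]
  for (lane in names(lanes)) {
    fr <- filter_fragments(lanes[[lane]]$fragments, fcfg,
                           is_input = lane == "input")
    fr <- deduplicate(fr, cap = fcfg$duplicate_cap)
    mp <- midpoints(fr)
    write_fragments(mp, add_file("fragments",
                                 file.path(outdir, paste0("midpoints_", lane, ".tsv"))))
    mids[[lane]] <- split(mp, mp$sample_id)
  }

  # --- profiles -----------------------------------------------------------
  log_stage("stage profile")
  input_mids_all <- do.call(rbind, mids[["input"]])
  input_track <- build_track(input_mids_all, genome)
  input_profile <- tss_profile(input_track, genome, cfg$window)
  write_profile_tsv(input_profile,
                    add_file("profile", file.path(outdir, "tss_profile_input.tsv")))
  write_bedgraph(input_track,
                 add_file("profile", file.path(outdir, "track_input.bedgraph")))
  ratios <- list()
  for (lane in cfg$ip_marks) {
    ip_track <- build_track(do.call(rbind, mids[[lane]]), genome)
    ip_profile <- tss_profile(ip_track, genome, cfg$window)
    ratios[[lane]] <- mark_occupancy(ip_profile, input_profile)
    write_profile_tsv(ratios[[lane]],
                      add_file("profile",
                               file.path(outdir, paste0("occupancy_ratio_", lane, ".tsv"))))
  }

  # --- differential -------------------------------------------------------
  log_stage("stage diff")
  dmark <- cfg$diff_mark
  used <- sample_ids[grepl(paste0("^(", cfg$condition_a, "|", cfg$condition_b, ")_"),
                           sample_ids)]
  mlist <- c(setNames(lapply(used, function(s) mids[[dmark]][[s]]),
                      paste0("ip_", used)),
             setNames(lapply(used, function(s) mids[["input"]][[s]]),
                      paste0("input_", used)))
  mlist <- mlist[!vapply(mlist, is.null, logical(1))]
  sm <- data.frame(sample_id = names(mlist),
                   condition = sub("_rep\\d+$", "", sub("^(ip|input)_", "", names(mlist))),
                   is_input = grepl("^input_", names(mlist)),
                   pair_id = sub("^(ip|input)_", "", names(mlist)),
                   stringsAsFactors = FALSE)
  pcm <- build_position_counts(mlist, genome, cfg$window, sm)
  dcfg <- differential_config(cfg$lfc_threshold, cfg$lfdr_threshold)
  diff_res <- differential_occupancy(pcm, cfg$condition_a, cfg$condition_b, dcfg)
  write.table(diff_res,
              add_file("diff", file.path(outdir, "differential_positions.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # --- cryptic ------------------------------------------------------------
  cryptic_res <- NULL
  if (cfg$cage_tags_per_gene > 0) {
    log_stage("stage cryptic")
    tag_tables <- list()
    for (sid in names(truths)) {
      tag_tables[[sid]] <- simulate_cage_tags(
        genome, truths[[sid]], tags_per_gene = cfg$cage_tags_per_gene,
        internal_fraction_when_cryptic = cfg$cage_internal_fraction,
        baseline_internal_fraction = cfg$cage_baseline_fraction,
        seed = derive_seed(cfg$seed, "cage", match(sid, names(truths))),
        sample_id = sid)
    }
    tags <- filter_tss_reads(do.call(rbind, tag_tables))
    ic <- internal_counts(tags, genome)
    used_cols <- grepl(paste0("^(", cfg$condition_a, "|", cfg$condition_b, ")_"),
                       colnames(ic))
    conds <- sub("_rep\\d+$", "", colnames(ic)[used_cols])
    cryptic_res <- call_set2_dependent(ic[, used_cols, drop = FALSE],
                                       setNames(conds, colnames(ic)[used_cols]),
                                       condition_ref = cfg$condition_a,
                                       condition_alt = cfg$condition_b,
                                       padj_threshold = cfg$cage_padj_threshold)
    write.table(cryptic_res,
                add_file("cryptic", file.path(outdir, "cryptic_genes.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  log_stage("done: ", outdir)
  invisible(list(outdir = outdir, genome = genome, truths = truths,
                 lanes = lanes, demux = demux, input_profile = input_profile,
                 ratios = ratios, differential = diff_res,
                 cryptic = cryptic_res, manifest = manifest_path))
}
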