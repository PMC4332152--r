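#' Genome model: chromosome sizes plus gene coordinates
#'
#' A `genome_model` is the coordinate frame shared by the simulator and
#' all downstream profile/count operations: a set of chromosomes with
#' lengths, and a gene table giving for every gene its chromosome,
#' strand, transcription start site (TSS, 0-based) and length in bp.
#'
#' @param chromosomes data.frame with columns `name`, `length`.
#' @param genes data.frame with columns `gene_id`, `chromosome`,
#'   `strand` (`"+"` or `"-"`), `tss` (0-based bp) and `length` (bp).
#'   For a plus-strand gene the body spans `[tss, tss + length)`; for a
#'   minus-strand gene it spans `(tss - length, tss]`.
#' @return An object of class `genome_model`.
#' @export
genome_model <- function(chromosomes, genes) {
  stopifnot(is.data.frame(chromosomes), is.data.frame(genes))
  chromosomes$name <- as.character(chromosomes$name)
  chromosomes$length <- as.integer(chromosomes$length)
  genes$gene_id <- as.character(genes$gene_id)
  genes$chromosome <- as.character(genes$chromosome)
  if (anyDuplicated(genes$gene_id))
    stop("gene_id values must be unique")
  if (!all(genes$strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'")
  if (!all(genes$chromosome %in% chromosomes$name))
    stop("gene on unknown chromosome")
  clen <- chromosomes$length[match(genes$chromosome, chromosomes$name)]
  start <- ifelse(genes$strand == "+", genes$tss, genes$tss - genes$length + 1L)
  end <- start + genes$length  # half-open
  if (any(start < 0L) || any(end > clen))
    stop("every gene must lie fully within its chromosome")
  structure(list(chromosomes = chromosomes, genes = genes),
            class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("genome_model: %d chromosome(s) (%s bp), %d gene(s)\n",
              nrow(x$chromosomes),
              format(sum(x$chromosomes$length), big.mark = ","),
              nrow(x$genes)))
  invisible(x)
}

# genomic [start, end) of each gene body, 0-based half-open
gene_body_bounds <- function(genome) {
  g <- genome$genes
  start <- ifelse(g$strand == "+", g$tss, g$tss - g$length + 1L)
  data.frame(gene_id = g$gene_id, chromosome = g$chromosome,
             start = as.integer(start),
             end = as.integer(start + g$length),
             strand = g$strand, tss = g$tss,
             length = g$length, stringsAsFactors = FALSE)
}

chrom_length <- function(genome, chrom) {
  i <- match(chrom, genome$chromosomes$name)
  if (anyNA(i)) stop("unknown chromosome: ", paste(chrom[is.na(i)], collapse = ", "))
  genome$chromosomes$length[i]
}

#' Read / write a genome model as TSV
#'
#' Serialises the coordinate frame so that downstream stages can run
#' standalone: `<prefix>_chromosomes.tsv` (name, length) and
#' `<prefix>_genes.tsv` (gene_id, chromosome, strand, tss, length).
#'
#' @param genome a [genome_model()] (for writing).
#' @param prefix path prefix for the two TSV files.
#' @return `write_genome_model()` returns the two paths invisibly;
#'   `read_genome_model()` returns a [genome_model()].
#' @export
write_genome_model <- function(genome, prefix) {
  p1 <- paste0(prefix, "_chromosomes.tsv")
  p2 <- paste0(prefix, "_genes.tsv")
  write.table(genome$chromosomes, p1, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(genome$genes, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(chromosomes = p1, genes = p2))
}

#' @rdname write_genome_model
#' @export
read_genome_model <- function(prefix) {
  genome_model(
    read.table(paste0(prefix, "_chromosomes.tsv"), header = TRUE, sep = "\t",
               stringsAsFactors = FALSE),
    read.table(paste0(prefix, "_genes.tsv"), header = TRUE, sep = "\t",
               stringsAsFactors = FALSE))
}

#' Generate a random gene annotation
#'
#' Places non-overlapping genes sequentially along one or more
#' chromosomes, with random strands and log-normal gene lengths.
#' Chromosome lengths are auto-sized to fit the requested genes (plus a
#' margin wide enough that the usual -1000..+1500 TSS window is never
#' truncated) unless `chromosome_length` is supplied, in which case the
#' placement fails with a sizing error if the genes do not fit.
#'
#' Gene lengths are drawn from a log-normal with arithmetic mean
#' `gene_length_mean` and log-scale sd `gene_length_sdlog`; the heavy
#' right tail reproduces the long-gene minority that matters for
#' length-weighted cryptic-initiation assignment.
#'
#' @param n_chromosomes number of chromosomes.
#' @param n_genes total number of genes (>= 1), distributed round-robin
#'   across chromosomes.
#' @param gene_length_mean mean gene length in bp (>= 500).
#' @param seed integer seed; the same seed reproduces the same model.
#' @param gene_length_sdlog log-scale standard deviation of gene length.
#' @param intergenic_mean mean intergenic gap in bp (exponential, plus a
#'   fixed 200 bp spacer).
#' @param margin bp kept gene-free at each chromosome end.
#' @param chromosome_length optional fixed chromosome length in bp.
#' @return A [genome_model()].
#' @export
build_genome <- function(n_chromosomes, n_genes, gene_length_mean = 1500,
                         seed = 1L, gene_length_sdlog = 0.5,
                         intergenic_mean = 400, margin = 2000L,
                         chromosome_length = NULL) {
  stopifnot(n_chromosomes >= 1, n_genes >= 1)
  if (gene_length_mean < 500)
    stop("gene_length_mean must be >= 500 bp")
  withr::with_seed(as.integer(seed), {
    meanlog <- log(gene_length_mean) - gene_length_sdlog^2 / 2
    lens <- pmax(300L, as.integer(round(
      rlnorm(n_genes, meanlog = meanlog, sdlog = gene_length_sdlog))))
    strands <- sample(c("+", "-"), n_genes, replace = TRUE)
    gaps <- 200L + as.integer(round(rexp(n_genes, rate = 1 / intergenic_mean)))
    chrom_of <- rep_len(seq_len(n_chromosomes), n_genes)
    chroms <- data.frame(name = sprintf("chr%02d", seq_len(n_chromosomes)),
                         length = 0L, stringsAsFactors = FALSE)
    rows <- vector("list", n_genes)
    for (ci in seq_len(n_chromosomes)) {
      idx <- which(chrom_of == ci)
      pos <- as.integer(margin)
      for (j in idx) {
        start <- pos
        end <- start + lens[j]
        rows[[j]] <- data.frame(
          gene_id = sprintf("g%04d", j),
          chromosome = chroms$name[ci],
          strand = strands[j],
          tss = if (strands[j] == "+") start else end - 1L,
          length = lens[j], stringsAsFactors = FALSE)
        pos <- end + gaps[j]
      }
      needed <- pos + as.integer(margin)
      if (is.null(chromosome_length)) {
        chroms$length[ci] <- needed
      } else {
        if (needed > chromosome_length)
          stop(sprintf(
            "genome too small: chromosome %s needs %d bp to place %d gene(s), got %d",
            chroms$name[ci], needed, length(idx), chromosome_length))
        chroms$length[ci] <- as.integer(chromosome_length)
      }
    }
    genome_model(chroms, do.call(rbind, rows))
  })
}
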