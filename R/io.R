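#' Read an allc-style cytosine count table
#'
#' The allc dialect is a TSV with columns chrom, 1-based position, strand
#' (`+`/`-`), 3-mer context (e.g. `CGA`, `CHH`), methylated read count and
#' total read count. Records are validated; malformed rows are rejected
#' with their line number.
#'
#' @param path file path (plain TSV, no header by default).
#' @param header does the file carry a header line?
#' @return data.frame with columns `chrom`, `pos`, `strand`, `context`,
#'   `mc`, `n`.
#' @examples
#' f <- tempfile()
#' writeLines("chr1\t100\t+\tCGA\t3\t10", f)
#' read_allc(f)
#' @export
read_allc <- function(path, header = FALSE) {
  empty <- file.exists(path) && file.size(path) == 0
  dt <- if (empty) data.frame() else
    data.table::fread(path, header = header, sep = "\t",
                      data.table = FALSE)
  if (nrow(dt) == 0L)
    return(data.frame(chrom = character(0), pos = integer(0),
                      strand = character(0), context = character(0),
                      mc = integer(0), n = integer(0)))
  if (ncol(dt) < 6L)
    stop("allc table must have >= 6 columns (chrom, pos, strand, context, ",
         "mc, n); got ", ncol(dt))
  dt <- dt[, 1:6]
  names(dt) <- c("chrom", "pos", "strand", "context", "mc", "n")
  line <- seq_len(nrow(dt)) + as.integer(header)
  bad_strand <- !(dt$strand %in% c("+", "-"))
  if (any(bad_strand))
    stop("unknown strand symbol at line(s): ",
         paste(head(line[bad_strand], 5L), collapse = ", "))
  bad_num <- !is.finite(dt$mc) | !is.finite(dt$n) | dt$mc < 0 | dt$n < 0 |
    dt$mc > dt$n
  if (any(bad_num))
    stop("invalid counts (need 0 <= mc <= n) at line(s): ",
         paste(head(line[bad_num], 5L), collapse = ", "))
  if (any(dt$pos < 1))
    stop("positions must be >= 1 at line(s): ",
         paste(head(line[dt$pos < 1], 5L), collapse = ", "))
  dt$pos <- as.integer(dt$pos)
  dt$mc <- as.integer(dt$mc)
  dt$n <- as.integer(dt$n)
  dt
}

#' Write an allc-style table
#' @param sites data.frame as returned by [read_allc()] or
#'   [simulate_site_counts()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_allc <- function(sites, path) {
  utils::write.table(sites[, c("chrom", "pos", "strand", "context",
                               "mc", "n")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene intervals from a BED6 file
#'
#' BED is 0-based half-open on disk; the returned `GRanges` is 1-based
#' inclusive (the package-wide convention, shared with allc positions).
#' The BED name column becomes `gene_id`.
#'
#' @param path BED file path.
#' @return `GRanges` with a `gene_id` metadata column.
#' @export
read_genes_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  gr$gene_id <- if (!is.null(gr$name)) gr$name else
    sprintf("gene%04d", seq_along(gr))
  gr
}

#' Read transposable-element records from a GFF3 file
#'
#' @param path GFF3 path; the `family` attribute (or, failing that, the
#'   record type) labels each record's TE family.
#' @return `GRanges` with a `family` metadata column.
#' @export
read_te_gff <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF3")
  fam <- S4Vectors::mcols(gr)$family
  if (is.null(fam)) fam <- as.character(S4Vectors::mcols(gr)$type)
  gr$family <- as.character(fam)
  gr
}

#' Write every output of a simulation run to a directory
#'
#' Emits the standard plain-text formats: contig FASTA, gene BED6 (0-based
#' half-open), TE GFF3 with a `family` attribute, allc TSVs for each
#' condition, the expression counts TSV and a ground-truth gene table.
#' Byte-identical across runs with the same config.
#'
#' @param genome [simulate_genome()] result.
#' @param truths named list of `true_methylome` objects (names become file
#'   suffixes, e.g. `list(control = ..., kd = ...)`).
#' @param counts named list of allc data.frames, parallel to `truths`.
#' @param expression optional [simulate_expression()] result.
#' @param dir output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_sim_outputs <- function(genome, truths = list(), counts = list(),
                              expression = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c()
  fa <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome$seqs), fa)
  files["fasta"] <- fa

  bed <- file.path(dir, "genes.bed")
  g <- genome$genes
  utils::write.table(
    data.frame(chrom = as.character(GenomicRanges::seqnames(g)),
               start = GenomicRanges::start(g) - 1L,   # BED is 0-based
               end = GenomicRanges::end(g),
               name = g$gene_id, score = 0L,
               strand = as.character(GenomicRanges::strand(g))),
    bed, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  files["genes_bed"] <- bed

  gff <- file.path(dir, "tes.gff3")
  te <- genome$tes
  lines <- c("##gff-version 3",
             sprintf("%s\tmethex_sim\tdispersed_repeat\t%d\t%d\t.\t%s\t.\tfamily=%s",
                     as.character(GenomicRanges::seqnames(te)),
                     GenomicRanges::start(te), GenomicRanges::end(te),
                     as.character(GenomicRanges::strand(te)), te$family))
  writeLines(lines, gff)
  files["tes_gff"] <- gff

  for (nm in names(truths)) {
    tf <- file.path(dir, sprintf("truth_%s.tsv", nm))
    utils::write.table(truths[[nm]]$genes, tf, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files[paste0("truth_", nm)] <- tf
  }
  for (nm in names(counts)) {
    af <- file.path(dir, sprintf("allc_%s.tsv", nm))
    write_allc(counts[[nm]], af)
    files[paste0("allc_", nm)] <- af
  }
  if (!is.null(expression)) {
    cf <- file.path(dir, "counts.tsv")
    utils::write.table(data.frame(gene_id = rownames(expression$counts),
                                  expression$counts, check.names = FALSE),
                       cf, sep = "\t", quote = FALSE, row.names = FALSE)
    files["counts"] <- cf
  }
  invisible(files)
}
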