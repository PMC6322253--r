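#' Simulate a genome with gene, TE and spike-in annotation
#'
#' Draws random uniform DNA contigs plus one fully unmethylated spike-in
#' contig, then places strand-assigned, mutually non-overlapping gene and TE
#' intervals. Genes are kept at least `2 * flank_len` from contig ends so
#' that metaplot flanks never run off a contig; TEs are placed in the
#' remaining intergenic space. Deterministic given `config$seed`.
#'
#' @param config a [sim_config()] object.
#' @return An object of class `sim_genome`: a list with `seqs` (named
#'   character vector of contig sequences, spike-in last), `genes` and `tes`
#'   (`GRanges` with `gene_id` / `family` metadata), `spikein` (contig
#'   name), and the `config`.
#' @examples
#' g <- simulate_genome(sim_config(seed = 7, n_genes = 10, chrom_len = 4e4))
#' length(g$genes)
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  chrom_names <- sprintf("chr%d", seq_len(config$n_chrom))

  seqs <- with_seed(stream_seed(config$seed, "genome"), {
    s <- vapply(seq_len(config$n_chrom), function(i)
      paste(sample(c("A", "C", "G", "T"), config$chrom_len,
                   replace = TRUE), collapse = ""),
      character(1))
    sp <- paste(sample(c("A", "C", "G", "T"), config$spikein_len,
                       replace = TRUE), collapse = "")
    stats::setNames(c(s, sp), c(chrom_names, "spikein"))
  })

  genes <- with_seed(stream_seed(config$seed, "genes"), {
    place_genes(config, chrom_names)
  })

  tes <- with_seed(stream_seed(config$seed, "tes"), {
    place_tes(config, chrom_names, genes)
  })

  structure(list(seqs = seqs, genes = genes, tes = tes,
                 spikein = "spikein", config = config),
            class = "sim_genome")
}

#' @export
print.sim_genome <- function(x, ...) {
  cat("sim_genome:", length(x$seqs) - 1L, "contig(s) +",
      "spike-in;", length(x$genes), "genes,", length(x$tes), "TEs\n")
  invisible(x)
}

# Place n non-overlapping intervals of the given lengths uniformly in
# [lo, hi] (1-based, inclusive) by distributing the free slack into random
# gaps. Errors out when the intervals cannot fit.
place_intervals <- function(lens, lo, hi, what = "feature") {
  n <- length(lens)
  if (n == 0L)
    return(data.frame(start = integer(0), end = integer(0)))
  slack <- (hi - lo + 1L) - sum(lens)
  if (slack < 0L)
    stop("placement failure: cannot fit ", n, " ", what,
         " intervals (need ", sum(lens), " bp, have ", hi - lo + 1L,
         " bp)", call. = FALSE)
  props <- diff(c(0, sort(runif(n)), 1))
  gaps <- floor(props * slack)[seq_len(n)]
  starts <- lo + cumsum(gaps) + c(0L, cumsum(lens[-n]))
  data.frame(start = as.integer(starts),
             end = as.integer(starts + lens - 1L))
}

place_genes <- function(config, chrom_names) {
  n <- config$n_genes
  if (n == 0L)
    return(GenomicRanges::GRanges(character(0), IRanges::IRanges(),
                                  gene_id = character(0)))
  per <- rep(n %/% config$n_chrom, config$n_chrom)
  extra <- n %% config$n_chrom
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
  margin <- 2L * config$flank_len
  lo <- margin + 1L
  hi <- config$chrom_len - margin
  if (n > 0L && hi < lo)
    stop("placement failure: contig too short for 2*flank_len margins",
         call. = FALSE)
  out <- vector("list", config$n_chrom)
  for (i in seq_len(config$n_chrom)) {
    if (per[i] == 0L) next
    lens <- sample(seq(config$gene_len_range[1], config$gene_len_range[2]),
                   per[i], replace = TRUE)
    iv <- place_intervals(lens, lo, hi, "gene")
    iv$chrom <- chrom_names[i]
    iv$strand <- sample(c("+", "-"), per[i], replace = TRUE)
    out[[i]] <- iv
  }
  df <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  gr$gene_id <- sprintf("gene%04d", seq_along(gr))
  gr
}

place_tes <- function(config, chrom_names, genes) {
  fams <- rep(config$te_families, each = config$n_te_per_family)
  n <- length(fams)
  if (n == 0L)
    return(GenomicRanges::GRanges(character(0), IRanges::IRanges(),
                                  family = character(0)))
  # free segments = contigs minus gene bodies (spike-in carries no TEs)
  free <- list()
  for (ch in chrom_names) {
    g <- genes[as.character(GenomicRanges::seqnames(genes)) == ch]
    occ <- IRanges::IRanges(GenomicRanges::start(g),
                            GenomicRanges::end(g))
    gaps <- IRanges::setdiff(IRanges::IRanges(1L, config$chrom_len), occ)
    if (length(gaps))
      free[[ch]] <- data.frame(chrom = ch, start = IRanges::start(gaps),
                               end = IRanges::end(gaps))
  }
  free <- do.call(rbind, free)
  fams <- sample(fams)               # interleave families across the genome
  lens <- sample(seq(config$te_len_range[1], config$te_len_range[2]),
                 n, replace = TRUE)
  res <- vector("list", n)
  for (j in seq_len(n)) {
    room <- free$end - free$start + 1L - lens[j]
    ok <- which(room >= 0L)
    if (!length(ok))
      stop("placement failure: no intergenic segment fits a ", lens[j],
           " bp TE", call. = FALSE)
    seg <- if (length(ok) == 1L) ok else
      sample(ok, 1L, prob = room[ok] + 1L)
    start <- free$start[seg] + sample.int(room[seg] + 1L, 1L) - 1L
    end <- start + lens[j] - 1L
    res[[j]] <- data.frame(chrom = free$chrom[seg], start = start,
                           end = end, family = fams[j])
    # split the used segment
    left <- right <- NULL
    if (start > free$start[seg])
      left <- data.frame(chrom = free$chrom[seg], start = free$start[seg],
                         end = start - 1L)
    if (end < free$end[seg])
      right <- data.frame(chrom = free$chrom[seg], start = end + 1L,
                          end = free$end[seg])
    free <- rbind(free[-seg, ], left, right)
  }
  df <- do.call(rbind, res)
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                         strand = sample(c("+", "-"), n, replace = TRUE),
                         family = df$family)
}
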