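#' CPM expression filter
#'
#' Retains genes with counts-per-million at or above `min_cpm` in at least
#' `min_libs` libraries -- the standard pre-filter before differential
#' expression testing.
#'
#' @param counts integer matrix, genes x libraries (or a `count_matrix`).
#' @param min_cpm CPM threshold (default 1).
#' @param min_libs minimum number of qualifying libraries (default 2).
#' @return Named logical vector: `TRUE` for retained genes.
#' @examples
#' m <- matrix(c(10, 0, 12, 0), 2, 2,
#'             dimnames = list(c("a", "b"), c("l1", "l2")))
#' cpm_filter(m * 1L)
#' @export
cpm_filter <- function(counts, min_cpm = 1, min_libs = 2L) {
  counts <- as_count_mat(counts)
  if (ncol(counts) < 2L) stop("need at least 2 libraries")
  tot <- colSums(counts)
  if (any(tot == 0)) stop("library with zero total counts: ",
                          paste(colnames(counts)[tot == 0], collapse = ", "))
  cpm <- sweep(counts, 2L, tot, `/`) * 1e6
  rowSums(cpm >= min_cpm) >= min_libs
}

as_count_mat <- function(counts) {
  if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
}

#' FPKM expression summary with group means and log2 fold-change
#'
#' FPKM per gene and library is `count * 1e9 / (length_bp * library_total)`.
#' Group means are the per-condition averages of library FPKM; the per-gene
#' log2 fold-change is `log2(mean_kd / mean_control)` where a zero group
#' mean is replaced by half the smallest nonzero group mean (pseudo-value)
#' before taking the ratio. The CPM retention flag is carried along.
#'
#' @param counts a `count_matrix` from [simulate_expression()], or an
#'   integer matrix (then `lengths` and `groups` are required).
#' @param lengths named gene lengths in bp.
#' @param groups factor of `control` / `kd` per library.
#' @param min_cpm,min_libs passed to [cpm_filter()].
#' @return List of class `expression_summary`: `fpkm` (matrix), `table`
#'   (data.frame `gene_id`, `mean_control`, `mean_kd`, `log2fc`,
#'   `retained`), `groups`.
#' @export
fpkm_summary <- function(counts, lengths = NULL, groups = NULL,
                         min_cpm = 1, min_libs = 2L) {
  if (inherits(counts, "count_matrix")) {
    lengths <- counts$lengths
    groups <- counts$groups
    counts <- counts$counts
  }
  counts <- as.matrix(counts)
  if (is.null(lengths) || is.null(groups))
    stop("`lengths` and `groups` are required with a plain matrix")
  lengths <- lengths[rownames(counts)]
  if (any(is.na(lengths) | lengths <= 0))
    stop("every gene needs a positive length")
  tot <- colSums(counts)
  if (any(tot == 0)) stop("library with zero total counts")
  fpkm <- sweep(counts, 2L, tot, `/`)
  fpkm <- sweep(fpkm, 1L, as.numeric(lengths), `/`) * 1e9
  mean_ctrl <- rowMeans(fpkm[, groups == "control", drop = FALSE])
  mean_kd <- rowMeans(fpkm[, groups == "kd", drop = FALSE])
  means <- c(mean_ctrl, mean_kd)
  pseudo <- if (any(means > 0)) min(means[means > 0]) / 2 else 1
  l2fc <- log2(ifelse(mean_kd == 0, pseudo, mean_kd) /
               ifelse(mean_ctrl == 0, pseudo, mean_ctrl))
  tab <- data.frame(gene_id = rownames(counts),
                    mean_control = mean_ctrl, mean_kd = mean_kd,
                    log2fc = l2fc,
                    retained = cpm_filter(counts, min_cpm, min_libs),
                    stringsAsFactors = FALSE)
  structure(list(fpkm = fpkm, table = tab, groups = groups),
            class = "expression_summary")
}

#' @export
print.expression_summary <- function(x, ...) {
  cat("expression_summary:", nrow(x$table), "genes,",
      sum(x$table$retained), "retained by the CPM filter\n")
  invisible(x)
}

#' Collapse neighbouring same-family TE records into loci
#'
#' Overlapping or book-ended records of one family are merged into a
#' single locus; records of different families never merge, even when
#' interleaved.
#'
#' @param tes `GRanges` with a `family` metadata column (e.g. from
#'   [read_te_gff()]).
#' @return `GRanges` of merged loci with `family` and `locus_id` columns.
#' @export
collapse_te_gff <- function(tes) {
  fam <- tes$family
  if (is.null(fam)) stop("`tes` must carry a `family` metadata column")
  merged <- lapply(split(tes, fam), function(g) {
    r <- GenomicRanges::reduce(g, ignore.strand = TRUE)
    r$family <- unique(g$family)
    r
  })
  out <- sort(do.call(c, unname(merged)), ignore.strand = TRUE)
  out$locus_id <- sprintf("%s_%04d", out$family,
                          stats::ave(seq_along(out), out$family,
                                     FUN = seq_along))
  out
}

#' Select the most abundant TE families
#'
#' Families are ranked by their number of collapsed loci at or above
#' `min_len` bp; ties break alphabetically.
#'
#' @param loci collapsed loci from [collapse_te_gff()].
#' @param min_len minimum locus length (default 500 bp).
#' @param top number of families to return (default 10).
#' @return Character vector of family names, most abundant first.
#' @export
select_top_te <- function(loci, min_len = 500L, top = 10L) {
  keep <- loci[GenomicRanges::width(loci) >= min_len]
  if (!length(keep)) return(character(0))
  tab <- sort(table(keep$family), decreasing = TRUE)
  names(tab)[seq_len(min(top, length(tab)))]
}

#' TE expression as RPKM
#'
#' Per-locus RPKM is `count * 1e9 / (locus_length_bp * mapped_total)`. The
#' per-million-only variant without length normalisation (`rpm`) is also
#' reported, and loci are additionally aggregated per family (family RPKM
#' uses the family's pooled counts over its pooled length).
#'
#' @param locus_counts named numeric vector of reads per locus (names =
#'   `locus_id`), e.g. BED-intersection counts.
#' @param loci collapsed loci from [collapse_te_gff()].
#' @param mapped_total mapped library size (reads).
#' @return List of class `te_expression`: `loci` (data.frame `locus_id`,
#'   `family`, `length`, `count`, `rpkm`, `rpm`) and `families`
#'   (aggregated).
#' @export
te_rpkm <- function(locus_counts, loci, mapped_total) {
  if (mapped_total <= 0) stop("`mapped_total` must be positive")
  ids <- loci$locus_id
  cnt <- locus_counts[ids]
  cnt[is.na(cnt)] <- 0
  len <- GenomicRanges::width(loci)
  per <- data.frame(locus_id = ids, family = loci$family, length = len,
                    count = as.numeric(cnt),
                    rpkm = as.numeric(cnt) * 1e9 / (len * mapped_total),
                    rpm = as.numeric(cnt) * 1e6 / mapped_total,
                    stringsAsFactors = FALSE)
  fam_cnt <- tapply(per$count, per$family, sum)
  fam_len <- tapply(per$length, per$family, sum)
  fams <- data.frame(family = names(fam_cnt),
                     n_loci = as.integer(table(per$family)[names(fam_cnt)]),
                     length = as.numeric(fam_len),
                     count = as.numeric(fam_cnt),
                     rpkm = as.numeric(fam_cnt) * 1e9 /
                       (as.numeric(fam_len) * mapped_total),
                     rpm = as.numeric(fam_cnt) * 1e6 / mapped_total,
                     stringsAsFactors = FALSE)
  structure(list(loci = per, families = fams), class = "te_expression")
}

#' One-sided rank test for TE reactivation
#'
#' Mann-Whitney (Wilcoxon rank-sum) test of whether knockdown TE
#' expression is stochastically greater than control (alternative:
#' `kd > control`). With fully tied inputs the test is degenerate and
#' `p = 1` is returned with a warning.
#'
#' @param rpkm_kd,rpkm_ctrl numeric RPKM distributions for the two
#'   conditions.
#' @return List with `p`, `statistic` (U), and the sample sizes.
#' @export
te_rank_test <- function(rpkm_kd, rpkm_ctrl) {
  if (!length(rpkm_kd) || !length(rpkm_ctrl))
    stop("need at least one locus per condition")
  if (length(unique(c(rpkm_kd, rpkm_ctrl))) == 1L) {
    warning("all values tied; rank test degenerate, p = 1")
    return(list(p = 1, statistic = NA_real_,
                n_kd = length(rpkm_kd), n_ctrl = length(rpkm_ctrl)))
  }
  wt <- suppressWarnings(stats::wilcox.test(rpkm_kd, rpkm_ctrl,
                                            alternative = "greater"))
  list(p = wt$p.value, statistic = unname(wt$statistic),
       n_kd = length(rpkm_kd), n_ctrl = length(rpkm_ctrl))
}

#' Load differential-expression significance from a table
#'
#' Consumes the output of an upstream DE pipeline (gene, log2FC, FDR) and
#' flags genes as differentially expressed at `FDR < alpha`. Genes in
#' `universe` that are absent from the table are non-DEG (reported via a
#' message).
#'
#' @param x path to a TSV with header, or a data.frame; must contain
#'   columns `gene` (or `gene_id`), `log2FC` and `FDR`.
#' @param alpha FDR threshold (default 0.05).
#' @param universe optional character vector of gene ids to report over.
#' @return data.frame `gene_id`, `log2FC`, `FDR`, `deg` (logical).
#' @export
load_deg_table <- function(x, alpha = 0.05, universe = NULL) {
  tab <- if (is.character(x))
    data.table::fread(x, sep = "\t", data.table = FALSE) else
      as.data.frame(x)
  nm <- names(tab)
  if ("gene" %in% nm && !"gene_id" %in% nm)
    names(tab)[nm == "gene"] <- "gene_id"
  need <- c("gene_id", "log2FC", "FDR")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("DEG table lacks required column(s): ",
         paste(miss, collapse = ", "))
  out <- data.frame(gene_id = as.character(tab$gene_id),
                    log2FC = as.numeric(tab$log2FC),
                    FDR = as.numeric(tab$FDR),
                    stringsAsFactors = FALSE)
  out$deg <- !is.na(out$FDR) & out$FDR < alpha
  if (!is.null(universe)) {
    absent <- setdiff(universe, out$gene_id)
    if (length(absent))
      message(length(absent), " gene(s) absent from the DEG table; ",
              "treated as non-DEG")
    add <- data.frame(gene_id = absent, log2FC = NA_real_, FDR = NA_real_,
                      deg = FALSE, stringsAsFactors = FALSE)
    out <- rbind(out[out$gene_id %in% universe, , drop = FALSE], add)
  }
  out
}

#' Stand-in two-group differential-expression test
#'
#' A substitute for a full upstream DE pipeline when only counts are at
#' hand: the classic exact negative-binomial two-group test (via edgeR's
#' `exactTest` with TMM normalisation and common/tagwise dispersion),
#' followed by BH correction. Intended for simulation studies; real
#' analyses should consume a dedicated DE pipeline's table through
#' [load_deg_table()].
#'
#' @param counts integer matrix or `count_matrix`.
#' @param groups factor of `control` / `kd` per library (taken from a
#'   `count_matrix` automatically).
#' @param min_cpm,min_libs CPM pre-filter passed to [cpm_filter()].
#' @return data.frame `gene_id`, `log2FC`, `PValue`, `FDR` (filtered genes
#'   only).
#' @export
de_standin_test <- function(counts, groups = NULL, min_cpm = 1,
                            min_libs = 2L) {
  if (inherits(counts, "count_matrix")) {
    groups <- counts$groups
    counts <- counts$counts
  }
  if (is.null(groups)) stop("`groups` is required")
  keep <- cpm_filter(counts, min_cpm, min_libs)
  y <- edgeR::DGEList(counts = counts[keep, , drop = FALSE],
                      group = groups)
  y <- edgeR::calcNormFactors(y)
  y <- suppressMessages(edgeR::estimateDisp(y))
  et <- edgeR::exactTest(y, pair = c("control", "kd"))
  tab <- et$table
  data.frame(gene_id = rownames(tab), log2FC = tab$logFC,
             PValue = tab$PValue,
             FDR = stats::p.adjust(tab$PValue, method = "BH"),
             stringsAsFactors = FALSE)
}
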