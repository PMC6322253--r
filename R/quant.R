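#' Weighted methylation level of a site set
#'
#' The weighted level is the total number of methylated reads divided by
#' the total number of reads over all sites in the set (a read-weighted
#' pooled estimate, not a mean of per-site levels). It is undefined -- and
#' returned as `NA`, distinct from 0 -- when the set carries no reads.
#'
#' @param sites allc-style data.frame with `mc` and `n` columns.
#' @param context context-class prefix to keep (default `"CG"`, matching
#'   contexts such as `CGA`/`CGT`); `NULL` keeps every site.
#' @return A single level in `[0, 1]`, or `NA` when total coverage is zero.
#' @examples
#' s <- data.frame(context = "CGA", mc = c(3, 7, 0), n = c(10, 10, 20))
#' weighted_level(s)   # 10 / 40
#' @export
weighted_level <- function(sites, context = "CG") {
  if (!is.null(context) && "context" %in% names(sites))
    sites <- sites[is_cg_prefix(sites$context, context), , drop = FALSE]
  wml(sites$mc, sites$n)
}

is_cg_prefix <- function(x, prefix) startsWith(as.character(x), prefix)

#' Estimate the bisulfite non-conversion rate from a spike-in contig
#'
#' The non-conversion rate is the weighted level over an unmethylated
#' spike-in (lambda-phage-like) contig: every methylated read there is a
#' conversion failure. A 95% Clopper-Pearson (exact binomial) interval is
#' attached.
#'
#' @param sites allc-style data.frame.
#' @param spikein name of the spike-in contig.
#' @param conf confidence level for the exact interval.
#' @return List with `rate`, `ci` (length-2 numeric), `mc`, `n`.
#' @examples
#' s <- data.frame(chrom = "spikein", pos = 1:2, context = "CGA",
#'                 mc = c(0, 1), n = c(5000, 5000))
#' estimate_nonconversion(s, "spikein")$rate
#' @export
estimate_nonconversion <- function(sites, spikein, conf = 0.95) {
  sp <- sites[sites$chrom == spikein, , drop = FALSE]
  if (nrow(sp) == 0L)
    stop("no sites found on spike-in contig '", spikein, "'")
  mc <- sum(as.numeric(sp$mc))
  n <- sum(as.numeric(sp$n))
  if (n == 0) stop("spike-in contig has zero coverage")
  bt <- stats::binom.test(round(mc), round(n), conf.level = conf)
  list(rate = mc / n, ci = as.numeric(bt$conf.int), mc = mc, n = n)
}

#' Pair plus/minus strand CG sites into CpG dyads
#'
#' A dyad is a plus-strand CG-context site at position `p` paired with the
#' minus-strand site at `p + 1` on the same contig. Sites with coverage on
#' only one strand of a dyad ("orphans") are reported separately: they are
#' excluded from symmetry analysis but remain usable for pooled levels.
#'
#' @param sites allc-style data.frame (CG-context sites are selected
#'   automatically).
#' @return List of class `dyad_set`: `dyads` (data.frame `chrom`, `pos`,
#'   `mc_plus`, `n_plus`, `mc_minus`, `n_minus`) and `orphans` (the
#'   unpaired site records).
#' @export
pair_dyads <- function(sites) {
  cg <- sites[is_cg_prefix(sites$context, "CG"), , drop = FALSE]
  plus <- cg[cg$strand == "+", , drop = FALSE]
  minus <- cg[cg$strand == "-", , drop = FALSE]
  key_p <- paste(plus$chrom, plus$pos + 1L)
  key_m <- paste(minus$chrom, minus$pos)
  i <- match(key_p, key_m)
  paired <- !is.na(i)
  dyads <- data.frame(
    chrom = plus$chrom[paired], pos = plus$pos[paired],
    mc_plus = plus$mc[paired], n_plus = plus$n[paired],
    mc_minus = minus$mc[i[paired]], n_minus = minus$n[i[paired]],
    stringsAsFactors = FALSE
  )
  orphans <- rbind(plus[!paired, , drop = FALSE],
                   minus[!(seq_len(nrow(minus)) %in% i[paired]), ,
                         drop = FALSE])
  structure(list(dyads = dyads, orphans = orphans), class = "dyad_set")
}

#' @export
print.dyad_set <- function(x, ...) {
  cat("dyad_set:", nrow(x$dyads), "dyads,", nrow(x$orphans), "orphans\n")
  invisible(x)
}

#' Strand symmetry of CpG dyad methylation
#'
#' For dyads with at least `min_cov` reads on each strand, computes the
#' per-strand levels, their Pearson correlation (the symmetry statistic:
#' high when maintenance methylation keeps both strands of a dyad in the
#' same state), and histograms of per-site and per-dyad levels for density
#' plotting.
#'
#' @param dyads a [pair_dyads()] result (or its `dyads` data.frame).
#' @param min_cov minimum reads per strand (default 3).
#' @param breaks histogram breakpoints on `[0, 1]`.
#' @return List of class `dyad_symmetry`: `levels` (data.frame
#'   `level_plus`, `level_minus`), `correlation` (`NA` and flagged via
#'   `correlation_defined` if fewer than 2 qualifying dyads or zero
#'   variance), `n_dyads`, `site_density` and `dyad_density` (histogram
#'   counts).
#' @export
dyad_symmetry_summary <- function(dyads, min_cov = 3L,
                                  breaks = seq(0, 1, by = 0.05)) {
  d <- if (inherits(dyads, "dyad_set")) dyads$dyads else dyads
  keep <- d$n_plus >= min_cov & d$n_minus >= min_cov
  d <- d[keep, , drop = FALSE]
  lev <- data.frame(level_plus = d$mc_plus / d$n_plus,
                    level_minus = d$mc_minus / d$n_minus)
  defined <- nrow(lev) >= 2L &&
    stats::var(lev$level_plus) > 0 && stats::var(lev$level_minus) > 0
  r <- if (defined) stats::cor(lev$level_plus, lev$level_minus) else NA_real_
  if (!defined && nrow(lev) > 0L)
    warning("dyad correlation undefined (<2 qualifying dyads or zero ",
            "variance)")
  site_lev <- c(lev$level_plus, lev$level_minus)
  dyad_lev <- (d$mc_plus + d$mc_minus) / (d$n_plus + d$n_minus)
  hcut <- function(x) {
    if (!length(x)) return(stats::setNames(integer(length(breaks) - 1L),
                                           head(breaks, -1L)))
    table(cut(x, breaks = breaks, include.lowest = TRUE))
  }
  structure(list(levels = lev, correlation = r,
                 correlation_defined = defined, n_dyads = nrow(lev),
                 site_density = hcut(site_lev),
                 dyad_density = hcut(dyad_lev)),
            class = "dyad_symmetry")
}

#' @export
print.dyad_symmetry <- function(x, ...) {
  cat("dyad_symmetry:", x$n_dyads, "dyads; Pearson r =",
      if (x$correlation_defined) format(x$correlation, digits = 3)
      else "undefined", "\n")
  invisible(x)
}

#' Weighted methylation level per genomic compartment
#'
#' Assigns every site to exactly one compartment with precedence
#' gene > TE > intergenic (the spike-in contig, when named, forms its own
#' compartment), then reports the weighted level, covered-site count and
#' read total per compartment plus a genome-wide row. An optional exon
#' annotation adds an `exonic` summary row computed over genic sites; it is
#' informational and not part of the disjoint partition.
#'
#' @param sites allc-style data.frame (CG context filtered by default).
#' @param genes,tes,exons `GRanges` annotations (1-based inclusive), or
#'   `NULL`.
#' @param spikein optional spike-in contig name.
#' @param context context prefix filter (default `"CG"`).
#' @return data.frame of class `region_levels` with columns `compartment`,
#'   `level`, `sites_covered`, `total_reads`.
#' @export
compartment_levels <- function(sites, genes = NULL, tes = NULL,
                               exons = NULL, spikein = NULL,
                               context = "CG") {
  if (!is.null(context) && "context" %in% names(sites))
    sites <- sites[is_cg_prefix(sites$context, context), , drop = FALSE]
  check_annotation_contigs(sites, list(genes = genes, tes = tes,
                                       exons = exons))
  comp <- rep("intergenic", nrow(sites))
  if (!is.null(spikein)) comp[sites$chrom == spikein] <- "spikein"
  gr <- sites_granges(sites)
  if (!is.null(tes) && length(tes)) {
    hit <- GenomicRanges::findOverlaps(gr, tes, select = "first")
    comp[!is.na(hit) & comp == "intergenic"] <- "te"
  }
  if (!is.null(genes) && length(genes)) {
    hit <- GenomicRanges::findOverlaps(gr, genes, select = "first")
    comp[!is.na(hit)] <- "genic"
  }
  lev_row <- function(idx, label) {
    sub <- sites[idx, , drop = FALSE]
    data.frame(compartment = label, level = wml(sub$mc, sub$n),
               sites_covered = sum(sub$n > 0),
               total_reads = sum(as.numeric(sub$n)),
               stringsAsFactors = FALSE)
  }
  labs <- intersect(c("genic", "te", "intergenic", "spikein"), unique(comp))
  out <- do.call(rbind, lapply(labs, function(l) lev_row(comp == l, l)))
  if (!is.null(exons) && length(exons)) {
    hit <- GenomicRanges::findOverlaps(gr, exons, select = "first")
    out <- rbind(out, lev_row(!is.na(hit), "exonic"))
  }
  out <- rbind(out, lev_row(rep(TRUE, nrow(sites)), "genome"))
  class(out) <- c("region_levels", "data.frame")
  out
}

check_annotation_contigs <- function(sites, annots) {
  known <- unique(sites$chrom)
  for (nm in names(annots)) {
    a <- annots[[nm]]
    if (is.null(a) || length(a) == 0L) next
    bad <- setdiff(unique(as.character(GenomicRanges::seqnames(a))), known)
    if (length(bad))
      stop("annotation '", nm, "' refers to contig(s) absent from the ",
           "site table: ", paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}
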