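#' Background methylation level from coding sequence
#'
#' The null rate for the methylated-gene binomial test: the weighted
#' methylation level over all CG sites that fall inside coding regions.
#' Because a fully unconverted-free background would make the binomial test
#' degenerate, the estimate is floored at `floor` -- typically the
#' estimated bisulfite non-conversion rate, the assay's error floor.
#'
#' @param sites allc-style data.frame.
#' @param coding `GRanges` of coding regions (1-based inclusive).
#' @param floor lower bound for the returned rate (default `1e-6`); pass
#'   the [estimate_nonconversion()] rate when available.
#' @param context context prefix filter.
#' @return Background rate `p0` in `(0, 1)`.
#' @export
background_level <- function(sites, coding, floor = 1e-6, context = "CG") {
  if (is.null(coding) || length(coding) == 0L)
    stop("coding annotation is empty")
  if (!is.null(context) && "context" %in% names(sites))
    sites <- sites[is_cg_prefix(sites$context, context), , drop = FALSE]
  hit <- GenomicRanges::findOverlaps(sites_granges(sites), coding,
                                     select = "first")
  sub <- sites[!is.na(hit), , drop = FALSE]
  if (sum(as.numeric(sub$n)) == 0)
    stop("zero coverage over coding regions; cannot estimate background")
  max(wml(sub$mc, sub$n), floor)
}

#' Classify genes as CG-methylated by a binomial test
#'
#' Reads over each gene's CG sites are pooled and tested against the
#' coding-sequence background `p0` with a one-sided binomial test
#' (alternative: methylation above background),
#' `p = P[Bin(sum n, p0) >= sum mc]`. Genes with fewer than `min_reads`
#' total reads or fewer than `min_sites` covered CG sites are
#' `indeterminate` and excluded from the multiplicity correction;
#' Benjamini-Hochberg q-values are computed across the determinate genes,
#' and a gene is called `methylated` when `q < alpha`. Sites shared by
#' overlapping genes count toward each gene.
#'
#' @param sites allc-style data.frame.
#' @param genes `GRanges` with a `gene_id` metadata column (1-based
#'   inclusive; gene extent is the start-to-stop-codon interval).
#' @param p0 background rate in `(0, 1)`, from [background_level()].
#' @param min_reads,min_sites coverage thresholds (default 20 reads over 20
#'   covered CG sites).
#' @param alpha FDR threshold for the methylated call.
#' @param context context prefix filter.
#' @return data.frame of class `meth_calls`: `gene_id`, `mc`, `n`, `sites`
#'   (covered CG sites), `level`, `p`, `q`, `status` in
#'   `{methylated, unmethylated, indeterminate}`.
#' @seealso [drop_false_negatives()] for the post-hoc drop rule,
#'   [compare_status()] for cross-condition comparison.
#' @export
classify_genes <- function(sites, genes, p0, min_reads = 20L,
                           min_sites = 20L, alpha = 0.05,
                           context = "CG") {
  if (!is.numeric(p0) || length(p0) != 1L || p0 <= 0 || p0 >= 1)
    stop("`p0` must be a single rate strictly inside (0, 1)")
  if (!is.null(context) && "context" %in% names(sites))
    sites <- sites[is_cg_prefix(sites$context, context), , drop = FALSE]
  ids <- genes$gene_id
  if (is.null(ids)) stop("`genes` must carry a `gene_id` metadata column")

  hits <- GenomicRanges::findOverlaps(sites_granges(sites), genes)
  si <- S4Vectors::queryHits(hits)
  gi <- S4Vectors::subjectHits(hits)
  acc <- function(x) {
    v <- rep(0, length(ids))
    if (length(gi)) {
      s <- tapply(x[si], gi, sum)
      v[as.integer(names(s))] <- as.numeric(s)
    }
    v
  }
  mc <- acc(sites$mc)
  n <- acc(sites$n)
  covered <- acc(as.integer(sites$n > 0))

  p <- ifelse(n > 0, pbinom(mc - 1, n, p0, lower.tail = FALSE), NA_real_)
  determinate <- n >= min_reads & covered >= min_sites
  q <- rep(NA_real_, length(ids))
  q[determinate] <- stats::p.adjust(p[determinate], method = "BH")
  status <- ifelse(!determinate, "indeterminate",
                   ifelse(q < alpha, "methylated", "unmethylated"))
  out <- data.frame(gene_id = ids, mc = mc, n = n, sites = covered,
                    level = ifelse(n > 0, mc / n, NA_real_),
                    p = p, q = q, status = status,
                    stringsAsFactors = FALSE)
  attr(out, "p0") <- p0
  attr(out, "alpha") <- alpha
  class(out) <- c("meth_calls", "data.frame")
  out
}

#' @export
print.meth_calls <- function(x, ...) {
  tab <- table(factor(x$status, levels = c("methylated", "unmethylated",
                                           "dropped", "indeterminate")))
  cat("meth_calls:", nrow(x), "genes (p0 =",
      format(attr(x, "p0"), digits = 3), ")\n")
  print(tab)
  invisible(x)
}

#' @export
summary.meth_calls <- function(object, ...) {
  m <- object$status == "methylated"
  cat("Methylated genes:", sum(m), "of", nrow(object), "\n")
  if (any(m))
    cat("Methylated level range: [",
        format(min(object$level[m]), digits = 3), ",",
        format(max(object$level[m]), digits = 3), "]\n")
  invisible(object)
}

#' Drop likely false-negative unmethylated calls
#'
#' The binomial caller can leave a highly methylated gene formally
#' `unmethylated` when few of its sites reach significance. Rule: let `t`
#' be the lowest weighted level among genes called methylated; every
#' unmethylated gene whose level exceeds `t` is re-labelled `dropped` and
#' excluded from downstream analyses. Methylated calls are never changed.
#' A no-op when no gene is methylated.
#'
#' @param calls a [classify_genes()] result.
#' @return The calls with the drop rule applied; the threshold is attached
#'   as attribute `drop_threshold`.
#' @export
drop_false_negatives <- function(calls) {
  meth <- calls$status == "methylated"
  if (!any(meth)) return(calls)
  t <- min(calls$level[meth])
  drop <- calls$status == "unmethylated" & !is.na(calls$level) &
    calls$level > t
  calls$status[drop] <- "dropped"
  attr(calls, "drop_threshold") <- t
  calls
}

#' Compare methylation status between two conditions
#'
#' Partitions the shared gene universe into differentially methylated genes
#' (DMG: determinate in both conditions with differing status), similarly
#' methylated genes (SMG: methylated in both), unmethylated genes (UMG:
#' unmethylated in both) and `unclassified` (indeterminate or dropped in
#' either condition, or absent from one call set). The per-gene level
#' change `delta_level = level_B - level_A` is attached so level-based
#' definitions of differential methylation can also be applied.
#'
#' @param calls_A,calls_B [classify_genes()] results (e.g. control and
#'   knockdown).
#' @return data.frame of class `meth_comparison`: `gene_id`, `status_A`,
#'   `status_B`, `class`, `delta_level`; partition counts in attribute
#'   `counts`.
#' @export
compare_status <- function(calls_A, calls_B) {
  ids <- union(calls_A$gene_id, calls_B$gene_id)
  only <- c(setdiff(calls_A$gene_id, calls_B$gene_id),
            setdiff(calls_B$gene_id, calls_A$gene_id))
  if (length(only))
    message(length(only), " gene(s) present in only one call set; ",
            "left unclassified")
  ia <- match(ids, calls_A$gene_id)
  ib <- match(ids, calls_B$gene_id)
  sa <- calls_A$status[ia]
  sb <- calls_B$status[ib]
  det <- function(s) !is.na(s) & s %in% c("methylated", "unmethylated")
  cls <- rep("unclassified", length(ids))
  both <- det(sa) & det(sb)
  cls[both & sa != sb] <- "DMG"
  cls[both & sa == "methylated" & sb == "methylated"] <- "SMG"
  cls[both & sa == "unmethylated" & sb == "unmethylated"] <- "UMG"
  out <- data.frame(gene_id = ids, status_A = sa, status_B = sb,
                    class = cls,
                    delta_level = calls_B$level[ib] - calls_A$level[ia],
                    stringsAsFactors = FALSE)
  attr(out, "counts") <- table(factor(cls, levels = c("DMG", "SMG", "UMG",
                                                      "unclassified")))
  class(out) <- c("meth_comparison", "data.frame")
  out
}

#' @export
print.meth_comparison <- function(x, ...) {
  cat("meth_comparison:", nrow(x), "genes\n")
  print(attr(x, "counts"))
  invisible(x)
}
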