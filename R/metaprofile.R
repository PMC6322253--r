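#' Proportional windows over a feature body and fixed-length flanks
#'
#' Splits a feature body (start-to-stop-codon interval for genes) into `k`
#' near-equal windows -- the remainder of `length mod k` is spread one base
#' at a time over the first windows -- and each fixed-length flank into `k`
#' equal windows. Windows are numbered 1..3k from biologically upstream to
#' downstream: minus-strand features get the reversed numbering, so window
#' 1 is always the far upstream flank window. Flank windows running past a
#' contig end are truncated (possibly to emptiness, `start > end`).
#'
#' @param start,end 1-based inclusive feature interval.
#' @param strand `"+"` or `"-"`.
#' @param k windows per segment (default 20).
#' @param flank flank length in bp (default 1000).
#' @param contig_len contig length for flank truncation (default `Inf`).
#' @return data.frame with `window` (1..3k), `segment`
#'   (`upstream`/`body`/`downstream`), `start`, `end`.
#' @examples
#' w <- proportional_windows(1001, 3000, "+", k = 20, flank = 1000)
#' all(w$end - w$start + 1 == c(rep(50, 20), rep(100, 20), rep(50, 20)))
#' @export
proportional_windows <- function(start, end, strand = "+", k = 20L,
                                 flank = 1000L, contig_len = Inf) {
  stopifnot(end >= start, k >= 1L)
  tile <- function(lo, hi, k) {
    len <- hi - lo + 1L
    base <- len %/% k
    extra <- len %% k
    sizes <- rep(base, k) + c(rep(1L, extra), rep(0L, k - extra))
    ends <- lo - 1L + cumsum(sizes)
    data.frame(start = ends - sizes + 1L, end = ends)
  }
  up <- tile(start - flank, start - 1L, k)
  body <- tile(start, end, k)
  down <- tile(end + 1L, end + flank, k)
  w <- rbind(up, body, down)
  w$segment <- rep(c("upstream", "body", "downstream"), each = k)
  # truncate at contig bounds; fully clipped windows become empty
  w$start <- pmax(w$start, 1L)
  w$end <- pmin(w$end, contig_len)
  w$window <- if (identical(strand, "-")) rev(seq_len(3L * k))
              else seq_len(3L * k)
  if (identical(strand, "-"))
    w$segment <- rev(w$segment)
  w[order(w$window), c("window", "segment", "start", "end")]
}

#' Metaplot: pooled methylation profile over features
#'
#' Computes the weighted methylation level in each of `3k` proportional
#' windows (upstream flank, body, downstream flank) pooled across all
#' features, strand-aware. Window levels are read-weighted
#' (`sum mc / sum n` across features) by default; `pooled = FALSE` instead
#' averages per-feature window levels, weighting every feature equally.
#' Features shorter than `k` bp are skipped and counted.
#'
#' @param sites allc-style data.frame.
#' @param features `GRanges` (genes or TE loci).
#' @param k windows per segment.
#' @param flank flank length (bp).
#' @param contig_lens optional named vector of contig lengths for flank
#'   truncation.
#' @param pooled read-weighted pooling (default) vs mean of per-feature
#'   levels.
#' @param context context prefix filter.
#' @return data.frame of class `meta_profile`: `window`, `segment`, `mc`,
#'   `n`, `level`; attributes `n_features` (profiled) and `n_skipped`
#'   (shorter than `k`).
#' @export
meta_profile <- function(sites, features, k = 20L, flank = 1000L,
                         contig_lens = NULL, pooled = TRUE,
                         context = "CG") {
  if (!is.null(context) && "context" %in% names(sites))
    sites <- sites[is_cg_prefix(sites$context, context), , drop = FALSE]
  nw <- 3L * k
  mc_tot <- n_tot <- numeric(nw)
  per_feat <- if (!pooled) matrix(NA_real_, length(features), nw) else NULL
  n_skip <- 0L
  site_split <- split(sites[, c("pos", "mc", "n")], sites$chrom)
  segs <- rep(c("upstream", "body", "downstream"), each = k)
  f_chrom <- as.character(GenomicRanges::seqnames(features))
  f_start <- GenomicRanges::start(features)
  f_end <- GenomicRanges::end(features)
  f_strand <- as.character(GenomicRanges::strand(features))

  for (j in seq_along(features)) {
    if (f_end[j] - f_start[j] + 1L < k) { n_skip <- n_skip + 1L; next }
    ch <- f_chrom[j]
    ss <- site_split[[ch]]
    clen <- if (!is.null(contig_lens) && ch %in% names(contig_lens))
      contig_lens[[ch]] else Inf
    w <- proportional_windows(f_start[j], f_end[j], f_strand[j],
                              k = k, flank = flank, contig_len = clen)
    if (is.null(ss)) next
    # windows tile [start - flank, end + flank] contiguously in genomic
    # order; assign sites by interval lookup on the genomic-sorted windows
    wg <- w[order(w$start), ]
    lo <- min(wg$start)
    hi <- max(wg$end)
    sel <- ss$pos >= lo & ss$pos <= hi
    if (!any(sel)) next
    sp <- ss[sel, , drop = FALSE]
    idx <- findInterval(sp$pos, wg$start)
    keep <- sp$pos <= wg$end[idx]        # guard truncated/empty windows
    wi <- wg$window[idx[keep]]
    if (!length(wi)) next
    mc_w <- tapply(sp$mc[keep], wi, sum)
    n_w <- tapply(sp$n[keep], wi, sum)
    ii <- as.integer(names(mc_w))
    mc_tot[ii] <- mc_tot[ii] + as.numeric(mc_w)
    n_tot[ii] <- n_tot[ii] + as.numeric(n_w)
    if (!pooled) {
      lev <- rep(NA_real_, nw)
      lev[ii] <- as.numeric(mc_w) / as.numeric(n_w)
      per_feat[j, ] <- lev
    }
  }
  level <- if (pooled) ifelse(n_tot > 0, mc_tot / n_tot, NA_real_)
           else colMeans(per_feat, na.rm = TRUE)
  out <- data.frame(window = seq_len(nw), segment = segs,
                    mc = mc_tot, n = n_tot, level = level)
  attr(out, "n_features") <- length(features) - n_skip
  attr(out, "n_skipped") <- n_skip
  attr(out, "k") <- k
  class(out) <- c("meta_profile", "data.frame")
  out
}

#' @export
print.meta_profile <- function(x, ...) {
  cat("meta_profile:", attr(x, "n_features"), "features (",
      attr(x, "n_skipped"), "skipped );",
      "mean body level:",
      format(mean(x$level[x$segment == "body"], na.rm = TRUE),
             digits = 3), "\n")
  invisible(x)
}

#' Plot a metaplot profile
#'
#' Base-graphics line plot of window levels with body boundaries marked.
#'
#' @param x a [meta_profile()] result.
#' @param ... further arguments passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.meta_profile <- function(x, ...) {
  k <- attr(x, "k")
  plot(x$window, x$level, type = "l", xlab = "window",
       ylab = "weighted mCG level", ...)
  graphics::abline(v = c(k + 0.5, 2 * k + 0.5), lty = 2, col = "grey50")
  invisible(x)
}
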