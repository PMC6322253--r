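#' Expression by methylation decile
#'
#' Ranks methylated genes by weighted mCG level, cuts them into `n_bins`
#' near-equal quantile bins (ties broken by stable gene-id order), keeps
#' unmethylated genes as their own `UM` bin, and reports the mean of
#' log2-scale expression with a t-based 95% confidence interval per bin.
#' Under the null of no methylation-expression relationship the bin means
#' show no monotone trend.
#'
#' @param calls a [classify_genes()] result.
#' @param expression named numeric vector of expression values per gene
#'   (e.g. group-mean FPKM), or an `expression_summary` (then
#'   `expr_column` selects the column).
#' @param n_bins number of methylation bins (default 10).
#' @param min_fpkm genes below this expression value are excluded
#'   (default 0 keeps everything; the log transform applies a pseudo-value
#'   to zeros).
#' @param expr_column column of the `expression_summary` table to use.
#' @param conf confidence level of the interval.
#' @return data.frame of class `decile_summary`: `bin` (`UM`, `1`..`n`),
#'   `n_genes`, `mean_level`, `mean_expr` (log2 scale), `ci_lo`, `ci_hi`.
#' @export
decile_analysis <- function(calls, expression, n_bins = 10L, min_fpkm = 0,
                            expr_column = "mean_control", conf = 0.95) {
  expr <- expr_vector(expression, expr_column)
  df <- merge(as.data.frame(calls)[, c("gene_id", "level", "status")],
              data.frame(gene_id = names(expr), expr = unname(expr),
                         stringsAsFactors = FALSE),
              by = "gene_id")
  df <- df[df$status %in% c("methylated", "unmethylated") &
             df$expr >= min_fpkm, , drop = FALSE]
  meth <- df[df$status == "methylated", , drop = FALSE]
  if (nrow(meth) < n_bins)
    stop("only ", nrow(meth), " methylated genes; use fewer bins than ",
         n_bins)
  meth <- meth[order(meth$level, meth$gene_id), , drop = FALSE]
  sizes <- rep(nrow(meth) %/% n_bins, n_bins)
  extra <- nrow(meth) %% n_bins
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  meth$bin <- rep(as.character(seq_len(n_bins)), times = sizes)
  um <- df[df$status == "unmethylated", , drop = FALSE]
  um$bin <- "UM"
  all <- rbind(um, meth)
  all$lexpr <- log2_pseudo(all$expr)
  one <- function(b) {
    s <- all[all$bin == b, , drop = FALSE]
    m <- mean(s$lexpr)
    half <- if (nrow(s) > 1L)
      stats::qt(1 - (1 - conf) / 2, nrow(s) - 1L) *
        stats::sd(s$lexpr) / sqrt(nrow(s)) else NA_real_
    data.frame(bin = b, n_genes = nrow(s),
               mean_level = mean(s$level), mean_expr = m,
               ci_lo = m - half, ci_hi = m + half,
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(c("UM", as.character(seq_len(n_bins))), one))
  class(out) <- c("decile_summary", "data.frame")
  out
}

expr_vector <- function(expression, expr_column = "mean_control") {
  if (inherits(expression, "expression_summary")) {
    stats::setNames(expression$table[[expr_column]],
                    expression$table$gene_id)
  } else if (is.numeric(expression) && !is.null(names(expression))) {
    expression
  } else stop("`expression` must be a named numeric vector or an ",
              "expression_summary")
}

#' Regression of expression on continuous methylation level
#'
#' Ordinary least squares of log2 expression (pseudo-value applied to
#' zeros) on the weighted mCG level, over genes with expression above
#' `min_fpkm`. The raw slope p-value is reported along with a Bonferroni
#' significance flag at `0.05 / m`, where `m` is the number of regressions
#' in the family of analyses the call belongs to.
#'
#' @param calls a [classify_genes()] result (or any data.frame with
#'   `gene_id` and `level`).
#' @param expression as in [decile_analysis()].
#' @param min_fpkm exclusive lower bound on expression (default 0: keep
#'   genes with positive expression, matching the convention of regressing
#'   over expressed genes).
#' @param m Bonferroni family size (default 1).
#' @param statuses gene statuses eligible for the regression.
#' @param expr_column column of an `expression_summary` to use.
#' @return List of class `level_regression`: `slope`, `intercept`, `se`,
#'   `p`, `n`, `m`, `significant`, `defined` (`FALSE` when the mCG level
#'   has zero variance) and the fitted `model`.
#' @export
level_regression <- function(calls, expression, min_fpkm = 0, m = 1L,
                             statuses = c("methylated", "unmethylated"),
                             expr_column = "mean_control") {
  expr <- expr_vector(expression, expr_column)
  df <- merge(as.data.frame(calls)[, c("gene_id", "level", "status")],
              data.frame(gene_id = names(expr), expr = unname(expr),
                         stringsAsFactors = FALSE),
              by = "gene_id")
  df <- df[df$status %in% statuses & df$expr > min_fpkm &
             !is.na(df$level), , drop = FALSE]
  if (nrow(df) < 3L) stop("need at least 3 genes with expression above ",
                          min_fpkm)
  if (stats::var(df$level) == 0) {
    warning("zero variance in mCG level; slope undefined")
    return(structure(list(slope = NA_real_, intercept = NA_real_,
                          se = NA_real_, p = NA_real_, n = nrow(df),
                          m = m, significant = NA, defined = FALSE,
                          model = NULL),
                     class = "level_regression"))
  }
  df$lexpr <- log2_pseudo(df$expr)
  fit <- stats::lm(lexpr ~ level, data = df)
  co <- summary(fit)$coefficients
  p <- co["level", "Pr(>|t|)"]
  structure(list(slope = co["level", "Estimate"],
                 intercept = co["(Intercept)", "Estimate"],
                 se = co["level", "Std. Error"], p = p, n = nrow(df),
                 m = m, significant = p < 0.05 / m, defined = TRUE,
                 model = fit),
            class = "level_regression")
}

#' @export
print.level_regression <- function(x, ...) {
  if (!x$defined) {
    cat("level_regression: slope undefined (zero mCG variance), n =",
        x$n, "\n")
  } else {
    cat("level_regression: slope =", format(x$slope, digits = 3),
        " raw p =", format(x$p, digits = 3),
        if (x$significant) "[S]" else "[NS]",
        "(Bonferroni m =", x$m, "), n =", x$n, "\n")
  }
  invisible(x)
}

#' Methylation change versus expression change
#'
#' Joins a cross-condition methylation comparison with per-gene log2
#' fold-changes of expression: `delta_mcg = level_kd - level_control`
#' against `log2FC` from group-mean FPKM. Reports the paired values,
#' fixed-grid 2-D bin counts (for hexbin-style density plotting) and the
#' Spearman rank correlation.
#'
#' @param comparison a [compare_status()] result.
#' @param expression an `expression_summary` (uses its `log2fc` and
#'   `retained` columns) or a named numeric vector of log2 fold-changes.
#' @param classes comparison classes to include (default: all determinate
#'   classes).
#' @param retained_only with an `expression_summary`, keep CPM-retained
#'   genes only.
#' @param mcg_breaks,fc_breaks fixed grid breakpoints.
#' @return List of class `delta_delta`: `table` (data.frame `gene_id`,
#'   `delta_mcg`, `log2fc`, `class`), `grid` (2-D count matrix), `rho` and
#'   `rho_p` (Spearman), `n`.
#' @export
delta_delta <- function(comparison, expression,
                        classes = c("DMG", "SMG", "UMG"),
                        retained_only = TRUE,
                        mcg_breaks = seq(-1, 1, by = 0.05),
                        fc_breaks = seq(-12, 12, by = 0.5)) {
  if (inherits(expression, "expression_summary")) {
    tab <- expression$table
    if (retained_only) tab <- tab[tab$retained, , drop = FALSE]
    fc <- stats::setNames(tab$log2fc, tab$gene_id)
  } else fc <- expr_vector(expression)
  df <- merge(as.data.frame(comparison)[, c("gene_id", "class",
                                            "delta_level")],
              data.frame(gene_id = names(fc), log2fc = unname(fc),
                         stringsAsFactors = FALSE),
              by = "gene_id")
  df <- df[df$class %in% classes & !is.na(df$delta_level) &
             is.finite(df$log2fc), , drop = FALSE]
  names(df)[names(df) == "delta_level"] <- "delta_mcg"
  grid <- table(
    cut(pmin(pmax(df$delta_mcg, min(mcg_breaks)), max(mcg_breaks)),
        mcg_breaks, include.lowest = TRUE),
    cut(pmin(pmax(df$log2fc, min(fc_breaks)), max(fc_breaks)),
        fc_breaks, include.lowest = TRUE)
  )
  if (nrow(df) >= 3L && stats::var(df$delta_mcg) > 0 &&
      stats::var(df$log2fc) > 0) {
    ct <- suppressWarnings(stats::cor.test(df$delta_mcg, df$log2fc,
                                           method = "spearman"))
    rho <- unname(ct$estimate)
    rho_p <- ct$p.value
  } else {
    rho <- NA_real_
    rho_p <- NA_real_
  }
  structure(list(table = df[, c("gene_id", "delta_mcg", "log2fc",
                                "class")],
                 grid = grid, rho = rho, rho_p = rho_p, n = nrow(df)),
            class = "delta_delta")
}

#' @export
print.delta_delta <- function(x, ...) {
  cat("delta_delta:", x$n, "genes; Spearman rho =",
      format(x$rho, digits = 3), "\n")
  invisible(x)
}

#' Overlap of differential methylation and differential expression
#'
#' Cross-tabulates genes by methylation-change class (DMG versus
#' SMG-or-UMG) and expression-change status (DEG versus non-DEG), with row
#' percentages -- e.g. the share of differentially methylated genes whose
#' expression did not change.
#'
#' @param meth_class character vector per gene: `DMG`, `SMG`, `UMG`
#'   (anything else is excluded), or a [compare_status()] result.
#' @param deg logical vector per gene (parallel to `meth_class`), or a
#'   [load_deg_table()] data.frame matched by `gene_id`.
#' @return List of class `overlap_table`: `counts` (2x2 matrix), `row_pct`
#'   (row percentages; `NaN` for empty rows), `n`.
#' @export
overlap_analysis <- function(meth_class, deg) {
  if (inherits(meth_class, "meth_comparison")) {
    ids <- meth_class$gene_id
    cls <- meth_class$class
  } else {
    ids <- names(meth_class)
    cls <- as.character(meth_class)
  }
  if (is.data.frame(deg)) {
    stopifnot(!is.null(ids))
    deg <- deg$deg[match(ids, deg$gene_id)]
    deg[is.na(deg)] <- FALSE
  }
  keep <- cls %in% c("DMG", "SMG", "UMG")
  cls <- cls[keep]
  deg <- deg[keep]
  row_f <- factor(ifelse(cls == "DMG", "DMG", "SMG/UMG"),
                  levels = c("DMG", "SMG/UMG"))
  col_f <- factor(ifelse(deg, "DEG", "non-DEG"),
                  levels = c("DEG", "non-DEG"))
  counts <- table(row_f, col_f)
  row_pct <- sweep(counts, 1L, rowSums(counts), `/`) * 100
  structure(list(counts = unclass(counts),
                 row_pct = unclass(row_pct), n = sum(counts)),
            class = "overlap_table")
}

#' @export
print.overlap_table <- function(x, ...) {
  cat("overlap_table (", x$n, "genes ):\n")
  print(x$counts)
  cat("row percentages:\n")
  print(round(x$row_pct, 2))
  invisible(x)
}

#' Relative-expression matrix with hierarchical gene ordering
#'
#' Standardises each gene's per-library expression by its row maximum
#' (relative FPKM in `[0, 1]`) and orders genes by average-linkage
#' hierarchical clustering on Euclidean distances, for heatmap display of
#' expression changes in a gene set. All-zero rows are left as zeros and
#' flagged.
#'
#' @param fpkm numeric matrix, genes x libraries (e.g.
#'   `expression_summary$fpkm`).
#' @param gene_set optional character vector restricting the rows.
#' @return List of class `rel_expr_matrix`: `matrix` (standardised, rows in
#'   cluster order), `order` (row order), `hclust`, `zero_rows` (gene ids).
#' @export
relative_expression_matrix <- function(fpkm, gene_set = NULL) {
  m <- as.matrix(fpkm)
  if (!is.null(gene_set)) {
    miss <- setdiff(gene_set, rownames(m))
    if (length(miss)) stop("gene(s) not in the matrix: ",
                           paste(head(miss, 5L), collapse = ", "))
    m <- m[gene_set, , drop = FALSE]
  }
  if (nrow(m) == 0L) stop("empty gene set")
  rmax <- apply(m, 1L, max)
  zero <- rmax == 0
  if (any(zero)) warning(sum(zero), " all-zero row(s) left unscaled")
  rel <- m / ifelse(rmax == 0, 1, rmax)
  hc <- if (nrow(rel) > 2L)
    stats::hclust(stats::dist(rel, method = "euclidean"),
                  method = "average")
  else NULL
  ord <- if (is.null(hc)) seq_len(nrow(rel)) else hc$order
  structure(list(matrix = rel[ord, , drop = FALSE], order = ord,
                 hclust = hc, zero_rows = rownames(m)[zero]),
            class = "rel_expr_matrix")
}
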