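# Methylation-expression association: deciles, regression, delta-delta,
# overlap table and the relative-expression heatmap matrix.

make_assoc_fixture <- function(n_meth = 100, n_um = 50, seed = 1,
                               slope = 0) {
  set.seed(seed)
  ids <- sprintf("g%04d", seq_len(n_meth + n_um))
  level <- c(runif(n_meth, 0.2, 0.95), runif(n_um, 0, 0.01))
  status <- c(rep("methylated", n_meth), rep("unmethylated", n_um))
  calls <- data.frame(gene_id = ids, level = level, status = status,
                      stringsAsFactors = FALSE)
  expr <- 2 ^ (8 + slope * level + rnorm(length(ids), 0, 1))
  names(expr) <- ids
  list(calls = calls, expr = expr)
}

test_that("decile bins partition methylated genes into near-equal ordered
           bins plus a UM bin", {
  fx <- make_assoc_fixture(100, 37)
  dec <- decile_analysis(fx$calls, fx$expr)
  expect_identical(dec$bin, c("UM", as.character(1:10)))
  expect_identical(dec$n_genes, c(37L, rep(10L, 10)))
  expect_true(all(diff(dec$mean_level[-1]) > 0))   # ordered by level
  # sizes differ by <= 1 when not divisible
  fx2 <- make_assoc_fixture(103, 10)
  dec2 <- decile_analysis(fx2$calls, fx2$expr)
  expect_identical(sum(dec2$n_genes[-1]), 103L)
  expect_lte(diff(range(dec2$n_genes[-1])), 1L)
  # too few methylated genes
  fx3 <- make_assoc_fixture(7, 10)
  expect_error(decile_analysis(fx3$calls, fx3$expr), "fewer bins")
})

test_that("decile trend detection: flat under the null, monotone under
           planted coupling", {
  # bin means under the null are 10 iid noise values, so any single
  # Spearman is itself noisy; average the absolute trend over replicates
  rho0 <- vapply(1:5, function(s) {
    null <- make_assoc_fixture(2000, 100, seed = s)
    dnull <- decile_analysis(null$calls, null$expr)
    suppressWarnings(cor(seq_len(10), dnull$mean_expr[-1],
                         method = "spearman"))
  }, numeric(1))
  expect_lte(mean(abs(rho0)), 0.6)
  alt <- make_assoc_fixture(2000, 100, seed = 3, slope = -4)
  dalt <- decile_analysis(alt$calls, alt$expr)
  rho1 <- suppressWarnings(
    cor(seq_len(10), dalt$mean_expr[-1], method = "spearman"))
  expect_lt(rho1, -0.8)
  # CI brackets the bin mean
  expect_true(all(dalt$ci_lo <= dalt$mean_expr &
                    dalt$mean_expr <= dalt$ci_hi))
})

test_that("level regression matches closed-form OLS on a toy fixture and
           flags degeneracy", {
  calls <- data.frame(gene_id = c("a", "b", "c"),
                      level = c(0.1, 0.5, 0.9),
                      status = "methylated", stringsAsFactors = FALSE)
  expr <- c(a = 2, b = 8, c = 32)       # log2 = 1, 3, 5: exact line
  reg <- suppressWarnings(level_regression(calls, expr))
  x <- calls$level
  y <- log2(expr)
  slope_hat <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(reg$slope, slope_hat)
  expect_equal(reg$slope, 5)
  expect_lt(reg$p, 1e-6)                # perfect fit
  expect_true(reg$significant)
  # Bonferroni family size raises the bar
  noisy <- make_assoc_fixture(50, 0, seed = 4, slope = -1)
  r1 <- level_regression(noisy$calls, noisy$expr, m = 1)
  r20 <- level_regression(noisy$calls, noisy$expr, m = 20)
  expect_identical(r20$significant, r20$p < 0.05 / 20)
  expect_gte(as.integer(r1$significant), as.integer(r20$significant))
  # zero-variance mCG is flagged, not an error
  calls$level <- 0.5
  expect_warning(r0 <- level_regression(calls, expr), "zero variance")
  expect_false(r0$defined)
})

test_that("regression p-values are calibrated under the null", {
  ps <- vapply(1:50, function(r) {
    fx <- make_assoc_fixture(80, 0, seed = 100 + r)
    level_regression(fx$calls, fx$expr)$p
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.1)
})

test_that("delta-delta pairs methylation change with expression change", {
  cmp <- data.frame(gene_id = c("a", "b", "c", "d"),
                    class = c("DMG", "DMG", "UMG", "unclassified"),
                    delta_level = c(-0.5, -0.2, 0, -0.9),
                    stringsAsFactors = FALSE)
  fc <- c(a = -1, b = 0.5, c = 0, d = 3)
  dd <- delta_delta(cmp, fc)
  expect_identical(dd$n, 3L)                     # unclassified excluded
  expect_setequal(dd$table$gene_id, c("a", "b", "c"))
  expect_equal(sum(dd$grid), 3)
  # identical methylomes and counts: all points at (0, 0)
  cmp0 <- data.frame(gene_id = c("a", "b"), class = "UMG",
                     delta_level = 0)
  dd0 <- delta_delta(cmp0, c(a = 0, b = 0))
  expect_true(all(dd0$table$delta_mcg == 0 & dd0$table$log2fc == 0))
  expect_true(is.na(dd0$rho))                    # zero variance: flagged
})

test_that("overlap analysis reproduces row percentages and matches a
           brute-force cross-tabulation", {
  # worked example at published scale: 6590 DMGs of which 6484 non-DEG
  cls <- c(rep("DMG", 6590), rep("SMG", 21), rep("UMG", 5982))
  deg <- c(rep(c(TRUE, FALSE), c(106, 6484)),
           rep(FALSE, 21 + 5982))
  ov <- overlap_analysis(stats::setNames(cls, sprintf("g%d",
                                                      seq_along(cls))),
                         deg)
  expect_identical(unname(ov$counts["DMG", "non-DEG"]), 6484L)
  expect_equal(round(ov$row_pct["DMG", "non-DEG"], 2), 98.39)
  expect_equal(sum(ov$counts), length(cls))
  expect_equal(unname(rowSums(ov$row_pct)), c(100, 100))

  # no DEGs at all
  ov2 <- overlap_analysis(stats::setNames(rep("DMG", 10),
                                          sprintf("g%d", 1:10)),
                          rep(FALSE, 10))
  expect_equal(unname(ov2$row_pct["DMG", "non-DEG"]), 100)
  expect_true(is.nan(ov2$row_pct["SMG/UMG", "DEG"]))

  # random fixture vs table() oracle
  set.seed(10)
  cls_r <- sample(c("DMG", "SMG", "UMG", "unclassified"), 500,
                  replace = TRUE)
  deg_r <- sample(c(TRUE, FALSE), 500, replace = TRUE)
  ov3 <- overlap_analysis(stats::setNames(cls_r,
                                          sprintf("g%d", 1:500)), deg_r)
  keep <- cls_r != "unclassified"
  oracle <- table(ifelse(cls_r[keep] == "DMG", "DMG", "SMG/UMG"),
                  ifelse(deg_r[keep], "DEG", "non-DEG"))
  got <- unclass(ov3$counts)[rownames(oracle), colnames(oracle)]
  expect_equal(as.vector(got), as.vector(unclass(oracle)))
})

test_that("relative-expression matrix standardises rows and clusters
           coherent patterns together", {
  m <- rbind(g1 = c(2, 4, 8))
  rel <- relative_expression_matrix(m)
  expect_equal(unname(rel$matrix[1, ]), c(0.25, 0.5, 1))
  # permutation of replicate columns permutes columns only
  m2 <- rbind(g1 = c(2, 4, 8), g2 = c(1, 2, 4), g3 = c(8, 4, 2),
              g4 = c(4, 2, 1))
  colnames(m2) <- c("r1", "r2", "r3")
  rel2 <- relative_expression_matrix(m2)
  perm <- m2[, c(3, 1, 2)]
  rel_p <- relative_expression_matrix(perm)
  expect_equal(rel_p$matrix[, colnames(m2)], rel2$matrix[, colnames(m2)])
  # rising genes cluster apart from falling genes
  ord <- rownames(rel2$matrix)
  pos_up <- match(c("g1", "g2"), ord)
  pos_dn <- match(c("g3", "g4"), ord)
  expect_true(max(pos_up) < min(pos_dn) || max(pos_dn) < min(pos_up))
  # all-zero row flagged, left as zeros
  m3 <- rbind(m2, g5 = c(0, 0, 0))
  expect_warning(rel3 <- relative_expression_matrix(m3), "all-zero")
  expect_true(all(rel3$matrix["g5", ] == 0))
  expect_identical(rel3$zero_rows, "g5")
})

test_that("heatmap clustering heights match a naive average-linkage
           oracle", {
  set.seed(20)
  m <- matrix(runif(60), 10, 6,
              dimnames = list(sprintf("g%02d", 1:10), NULL))
  rel <- relative_expression_matrix(m)
  rmax <- apply(m, 1, max)
  sc <- m / rmax
  # naive average linkage on Euclidean distances
  d <- as.matrix(dist(sc))
  clusters <- as.list(seq_len(10))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); bh <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      h <- mean(d[clusters[[i]], clusters[[j]]])
      if (h < bh) { bh <- h; best <- c(i, j) }
    }
    heights <- c(heights, bh)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  expect_equal(sort(rel$hclust$height), sort(heights))
})
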