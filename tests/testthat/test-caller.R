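# Binomial methylated-gene caller: exact-tail oracle agreement, BH
# behaviour, thresholds, drop rule, calibration, power and comparison.

test_that("background level is the coding weighted level, floored", {
  coding <- GenomicRanges::GRanges("c1", IRanges::IRanges(c(1, 200),
                                                          c(100, 300)))
  s <- data.frame(chrom = "c1", pos = c(50L, 250L, 500L), strand = "+",
                  context = "CGA", mc = c(10L, 0L, 99L),
                  n = c(100L, 100L, 100L))
  expect_equal(background_level(s, coding), 0.05)  # (10+0)/(100+100)
  s$mc <- c(0L, 0L, 99L)
  expect_equal(background_level(s, coding, floor = 5e-4), 5e-4)
  expect_error(background_level(s[3, ], coding), "zero coverage")
  expect_error(background_level(s, NULL), "empty")
})

test_that("background on synthetic data matches the analytic mixture
           mean", {
  cfg <- sim_config(seed = 13, n_chrom = 2L, chrom_len = 3e5L,
                    n_genes = 120L, frac_methylated_genes = 0.4,
                    meth_level_dist = c(8, 2), depth_mean = 20,
                    spikein_len = 5000L)
  g <- simulate_genome(cfg)
  truth <- simulate_methylome(g, cfg)
  s <- simulate_site_counts(truth, cfg, "control")
  p0 <- background_level(s, g$genes, floor = 1e-6)
  # analytic: coverage-weighted genic truth mean + non-conversion leak
  mu <- mean(truth$dyads$level[truth$dyads$compartment == "genic"])
  expected <- mu + (1 - mu) * cfg$nonconversion_rate
  n_genic <- sum(truth$dyads$compartment == "genic") * 2 * cfg$depth_mean
  se <- sqrt(expected * (1 - expected) / n_genic)
  expect_lt(abs(p0 - expected), 3 * se + 0.01)
})

test_that("binomial p-values match the exact tail oracle to 1e-12 and BH
           matches the step-up oracle", {
  fx <- make_called_genes(60, sites_per_gene = 25, depth = 4,
                          level = seq(0.01, 0.9, length.out = 60),
                          seed = 5)
  p0 <- 0.05
  calls <- classify_genes(fx$sites, fx$genes, p0)
  for (i in seq_len(nrow(calls)))
    expect_equal(calls$p[i],
                 oracle_binom_tail(calls$mc[i], calls$n[i], p0),
                 tolerance = 1e-12)
  det <- calls$status != "indeterminate"
  expect_equal(calls$q[det], oracle_bh(calls$p[det]), tolerance = 1e-12)
  # BH monotonicity and q >= p
  expect_true(all(calls$q[det] >= calls$p[det] - 1e-15))
  o <- order(calls$p[det])
  expect_true(all(diff(calls$q[det][o]) >= -1e-15))
})

test_that("classification thresholds and edge cases behave as specified", {
  genes <- GenomicRanges::GRanges("c1",
    IRanges::IRanges(c(1, 1000, 2000), width = 500),
    gene_id = c("low_reads", "clean_unmeth", "strong_meth"))
  mk <- function(start, k, mc, n)
    data.frame(chrom = "c1", pos = start + 2L * (seq_len(k) - 1L),
               strand = "+", context = "CGA",
               mc = rep_len(mc, k), n = rep_len(n, k))
  s <- rbind(mk(1, 15, 1L, 1L),        # 15 reads < 20 -> indeterminate
             mk(1000, 25, 0L, 4L),     # mc=0 of 100
             mk(2000, 25, c(4L, 3L), 4L))  # ~90 of 100
  calls <- classify_genes(s, genes, p0 = 0.01)
  expect_identical(calls$status[calls$gene_id == "low_reads"],
                   "indeterminate")
  expect_identical(calls$status[calls$gene_id == "clean_unmeth"],
                   "unmethylated")
  expect_equal(calls$p[calls$gene_id == "clean_unmeth"], 1)
  expect_identical(calls$status[calls$gene_id == "strong_meth"],
                   "methylated")
  # a gene with zero covered sites is indeterminate, never an error
  genes2 <- c(genes, GenomicRanges::GRanges("c1",
    IRanges::IRanges(5000, 5500), gene_id = "no_sites"))
  calls2 <- classify_genes(s, genes2, p0 = 0.01)
  expect_identical(calls2$status[calls2$gene_id == "no_sites"],
                   "indeterminate")
  expect_error(classify_genes(s, genes, p0 = 0), "p0")
  expect_error(classify_genes(s, genes, p0 = 1), "p0")
})

test_that("null calibration: methylated-call fraction stays below alpha,
           and the caller has power at high levels", {
  p0 <- 0.05
  rates <- vapply(1:20, function(r) {
    fx <- make_called_genes(2000, sites_per_gene = 25, depth = 3,
                            level = p0, seed = 1000 + r)
    calls <- classify_genes(fx$sites, fx$genes, p0)
    det <- calls$status != "indeterminate"
    mean(calls$status[det] == "methylated")
  }, numeric(1))
  expect_lte(mean(rates), 0.05)

  fx <- make_called_genes(500, sites_per_gene = 25, depth = 3,
                          level = 0.8, seed = 2)
  calls <- classify_genes(fx$sites, fx$genes, p0)
  det <- calls$n >= 20 & calls$sites >= 20
  expect_gte(mean(calls$status[det] == "methylated"), 0.99)
})

test_that("call rate is monotone in true level and coverage", {
  p0 <- 0.05
  grid <- expand.grid(level = c(0.10, 0.2, 0.4), depth = c(1, 2, 4))
  rate <- mapply(function(lv, dp) {
    fx <- make_called_genes(300, sites_per_gene = 25, depth = dp,
                            level = lv, seed = round(lv * 100 + dp))
    calls <- classify_genes(fx$sites, fx$genes, p0)
    det <- calls$status != "indeterminate"
    mean(calls$status[det] == "methylated")
  }, grid$level, grid$depth)
  m <- matrix(rate, 3, 3)          # rows: level, cols: depth
  expect_true(all(apply(m, 2, diff) >= -0.02))   # non-decreasing in level
  expect_true(all(apply(m, 1, diff) >= -0.02))   # non-decreasing in depth
})

test_that("false-negative drop rule matches an exhaustive oracle and
           never touches methylated calls", {
  fx <- make_called_genes(120, sites_per_gene = 25, depth = 4,
                          level = runif(120, 0, 0.9), seed = 12)
  calls <- classify_genes(fx$sites, fx$genes, p0 = 0.05)
  dropped <- drop_false_negatives(calls)
  meth_lv <- calls$level[calls$status == "methylated"]
  if (length(meth_lv)) {
    t <- min(meth_lv)
    oracle <- calls$gene_id[calls$status == "unmethylated" &
                              calls$level > t]
    expect_setequal(dropped$gene_id[dropped$status == "dropped"], oracle)
  }
  expect_identical(dropped$status[calls$status == "methylated"],
                   calls$status[calls$status == "methylated"])

  # explicit rule application and the no-op case
  toy <- calls[1:3, ]
  toy$status <- c("methylated", "methylated", "unmethylated")
  toy$level <- c(0.6, 0.8, 0.7)
  expect_identical(drop_false_negatives(toy)$status[3], "dropped")
  toy$status <- rep("unmethylated", 3)
  expect_identical(drop_false_negatives(toy)$status, toy$status)
})

test_that("status comparison partitions genes and detects knockdown
           loss", {
  fx <- make_called_genes(40, sites_per_gene = 25, depth = 4,
                          level = rep(c(0.05, 0.8), 20), seed = 3)
  calls <- classify_genes(fx$sites, fx$genes, p0 = 0.05)
  cmp_same <- compare_status(calls, calls)
  expect_identical(unname(attr(cmp_same, "counts")["DMG"]), 0L)
  expect_equal(cmp_same$delta_level, rep(0, nrow(cmp_same)))

  # synthetic knockdown at f = 0.1: truly methylated, well-covered genes
  # flip to unmethylated against the control background
  cfg <- sim_config(seed = 17, n_chrom = 2L, chrom_len = 2.5e5L,
                    n_genes = 150L, gene_len_range = c(800L, 1600L),
                    depth_mean = 15, spikein_len = 5000L)
  g <- simulate_genome(cfg)
  truth <- simulate_methylome(g, cfg)
  kd <- apply_knockdown(truth, 0.1)
  sc <- simulate_site_counts(truth, cfg, "control")
  sk <- simulate_site_counts(kd, cfg, "kd")
  p0 <- background_level(sc, g$genes,
                         floor = estimate_nonconversion(sc,
                                                        "spikein")$rate)
  cc <- classify_genes(sc, g$genes, p0)
  ck <- classify_genes(sk, g$genes, p0)
  cmp <- compare_status(cc, ck)
  true_meth <- truth$genes$gene_id[truth$genes$class == "methylated"]
  covered <- cc$gene_id[cc$n >= 20 & cc$sites >= 20]
  target <- intersect(true_meth, covered)
  dmg_rate <- mean(cmp$class[match(target, cmp$gene_id)] == "DMG")
  expect_gte(dmg_rate, 0.9)

  # disjoint universes are logged and unclassified
  expect_message(cmp2 <- compare_status(cc[-1, ], ck), "unclassified")
  expect_identical(cmp2$class[cmp2$gene_id == cc$gene_id[1]],
                   "unclassified")
})
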