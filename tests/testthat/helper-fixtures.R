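# Shared fixtures, all built in code.

small_cfg <- function(seed = 11, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_chrom = 1L, chrom_len = 50000L, n_genes = 10L,
         gene_len_range = c(800L, 1500L), n_te_per_family = 3L,
         spikein_len = 5000L),
    list(...))
  do.call(sim_config, args)
}

# One simulated world, shared across read-only tests.
sim_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 101, n_chrom = 2L, chrom_len = 80000L,
                        n_genes = 40L, spikein_len = 20000L)
      g <- simulate_genome(cfg)
      truth <- simulate_methylome(g, cfg)
      cache <<- list(cfg = cfg, genome = g, truth = truth,
                     sites = simulate_site_counts(truth, cfg, "control"))
    }
    cache
  }
})

# Genes laid out on one synthetic contig with hand-controlled per-gene site
# counts: gene g gets `sites_per_gene` CG sites of given depth and level.
# Returns list(sites, genes) ready for classify_genes().
make_called_genes <- function(n_genes, sites_per_gene, depth, level,
                              seed = 1) {
  set.seed(seed)
  gene_span <- sites_per_gene * 10L
  starts <- (seq_len(n_genes) - 1L) * (gene_span + 100L) + 1L
  genes <- GenomicRanges::GRanges("chrU",
    IRanges::IRanges(starts, starts + gene_span - 1L))
  genes$gene_id <- sprintf("g%04d", seq_len(n_genes))
  lev <- rep(level, length.out = n_genes)
  pos <- unlist(lapply(starts, function(s)
    s + 10L * (seq_len(sites_per_gene) - 1L)))
  n <- rpois(length(pos), depth)
  mc <- rbinom(length(pos), n, rep(lev, each = sites_per_gene))
  sites <- data.frame(chrom = "chrU", pos = pos, strand = "+",
                      context = "CGA", mc = mc, n = n,
                      stringsAsFactors = FALSE)
  list(sites = sites, genes = genes)
}

# Independent oracle: one-sided upper binomial tail by explicit summation.
oracle_binom_tail <- function(mc, n, p0) {
  if (n == 0) return(NA_real_)
  sum(dbinom(seq(mc, n), n, p0))
}

# Independent oracle: Benjamini-Hochberg step-up q-values.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}
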