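#' Configuration for the synthetic WGBS + RNA-seq generator
#'
#' Bundles and validates every tunable of the synthetic-data generator. The
#' defaults describe the study system the generator emulates: an insect
#' genome with bimodal gene-body CG methylation (roughly 40% of genes
#' highly methylated, the rest unmethylated), moderately methylated
#' transposable elements, low intergenic methylation, an unmethylated
#' spike-in contig carrying only bisulfite non-conversion error (~0.05%),
#' ~10x per-site coverage, and a maintenance-methyltransferase knockdown
#' modelled as a cell mixture in which a fraction `retained_fraction` of
#' cells keeps the wild-type methylome and the remainder is fully
#' demethylated.
#'
#' @param seed master seed; every output kind draws from its own RNG stream
#'   derived from it, so resizing one output does not perturb the others.
#' @param n_chrom,chrom_len number and length (bp) of autosomal contigs.
#' @param n_genes number of genes, distributed across contigs.
#' @param gene_len_range min/max gene length (bp).
#' @param flank_len flank length (bp) used in metaplots; genes are kept at
#'   least `2 * flank_len` from contig ends.
#' @param n_te_per_family,te_families,te_len_range transposable-element
#'   annotation: copies per family, family names, length range (bp).
#' @param spikein_len length (bp) of the fully unmethylated spike-in contig
#'   (a lambda-phage-like conversion control).
#' @param frac_methylated_genes probability that a gene belongs to the
#'   methylated class.
#' @param meth_level_dist `c(shape1, shape2)` of the Beta distribution for
#'   per-dyad true levels inside methylated-class genes; the default
#'   Beta(8, 2) has mean 0.8, emulating high, slightly variable gene-body
#'   methylation.
#' @param unmeth_level true level at every site of unmethylated-class genes.
#' @param te_level,intergenic_level true levels in TE bodies and intergenic
#'   space.
#' @param nonconversion_rate probability that an unmethylated cytosine reads
#'   out as methylated (failed bisulfite conversion).
#' @param depth_mean mean per-site, per-strand read depth (Poisson).
#' @param retained_fraction knockdown dilution factor f in `[0, 1]`: the
#'   fraction of cells retaining the wild-type methylome.
#' @param n_reps_per_group RNA-seq biological replicates per condition.
#' @param nb_mean_log_range range (log2 scale) for baseline mean counts.
#' @param nb_dispersion negative-binomial dispersion (squared biological
#'   coefficient of variation); 0 gives Poisson counts.
#' @param coupling_effect log2 fold-change of expression per unit change in
#'   gene methylation level; 0 (the default) decouples expression from
#'   methylation.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 20, chrom_len = 5e4)
#' cfg$retained_fraction
#' @export
sim_config <- function(seed = 1L,
                       n_chrom = 2L,
                       chrom_len = 100000L,
                       n_genes = 60L,
                       gene_len_range = c(1000L, 3000L),
                       flank_len = 1000L,
                       n_te_per_family = 8L,
                       te_families = c("Gypsy", "Jockey", "Chapaev"),
                       te_len_range = c(300L, 2000L),
                       spikein_len = 48500L,
                       frac_methylated_genes = 0.4,
                       meth_level_dist = c(8, 2),
                       unmeth_level = 0,
                       te_level = 0.4,
                       intergenic_level = 0.1,
                       nonconversion_rate = 5e-4,
                       depth_mean = 10,
                       retained_fraction = 0.15,
                       n_reps_per_group = 3L,
                       nb_mean_log_range = c(2, 10),
                       nb_dispersion = 0.1,
                       coupling_effect = 0) {
  cfg <- list(
    seed = as.integer(seed), n_chrom = as.integer(n_chrom),
    chrom_len = as.integer(chrom_len), n_genes = as.integer(n_genes),
    gene_len_range = as.integer(gene_len_range),
    flank_len = as.integer(flank_len),
    n_te_per_family = as.integer(n_te_per_family),
    te_families = as.character(te_families),
    te_len_range = as.integer(te_len_range),
    spikein_len = as.integer(spikein_len),
    frac_methylated_genes = frac_methylated_genes,
    meth_level_dist = as.numeric(meth_level_dist),
    unmeth_level = unmeth_level, te_level = te_level,
    intergenic_level = intergenic_level,
    nonconversion_rate = nonconversion_rate,
    depth_mean = depth_mean, retained_fraction = retained_fraction,
    n_reps_per_group = as.integer(n_reps_per_group),
    nb_mean_log_range = as.numeric(nb_mean_log_range),
    nb_dispersion = nb_dispersion, coupling_effect = coupling_effect
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  for (nm in c("frac_methylated_genes", "unmeth_level", "te_level",
               "intergenic_level", "nonconversion_rate",
               "retained_fraction"))
    stopifnot_proportion(cfg[[nm]], nm)
  if (cfg$n_chrom < 1L) stop("need at least one contig")
  if (cfg$n_genes < 0L) stop("`n_genes` must be non-negative")
  if (length(cfg$gene_len_range) != 2L ||
      cfg$gene_len_range[1] > cfg$gene_len_range[2] ||
      cfg$gene_len_range[1] < 1L)
    stop("`gene_len_range` must be an increasing positive pair")
  if (length(cfg$meth_level_dist) != 2L || any(cfg$meth_level_dist <= 0))
    stop("`meth_level_dist` must be two positive Beta shapes")
  if (cfg$depth_mean <= 0) stop("`depth_mean` must be positive")
  if (cfg$nb_dispersion < 0) stop("`nb_dispersion` must be non-negative")
  if (cfg$n_reps_per_group < 1L) stop("`n_reps_per_group` must be >= 1")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_chrom, "contig(s) x", x$chrom_len, "bp,",
      x$n_genes, "genes,", length(x$te_families), "TE families\n")
  cat("  methylated-gene fraction:", x$frac_methylated_genes,
      " Beta(", x$meth_level_dist[1], ",", x$meth_level_dist[2], ")\n")
  cat("  depth:", x$depth_mean, " non-conversion:", x$nonconversion_rate,
      " knockdown retained fraction:", x$retained_fraction, "\n")
  invisible(x)
}
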