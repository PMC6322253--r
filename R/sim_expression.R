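#' Simulate a two-group RNA-seq count matrix
#'
#' Negative-binomial gene counts for a control and a knockdown group.
#' Baseline means are drawn per gene on a log2 scale; the knockdown group
#' mean is multiplied by `2^(coupling_effect * delta_mcg)` where
#' `delta_mcg` is the gene's change in true mean methylation level between
#' the two methylomes. With `coupling_effect = 0` (the default) expression
#' is generated independently of methylation, which is the null the
#' association analyses are calibrated against; a nonzero value plants a
#' methylation-expression coupling for power studies.
#'
#' @param genome a [simulate_genome()] result (provides gene identities and
#'   lengths).
#' @param truth_control,truth_kd `true_methylome` objects for the two
#'   conditions (pass the same object twice for a single-condition design).
#' @param config the [sim_config()]; uses `n_reps_per_group`,
#'   `nb_mean_log_range`, `nb_dispersion`, `coupling_effect`.
#' @return An object of class `count_matrix`: list with integer `counts`
#'   (genes x libraries), `groups` (factor `control` / `kd` per library),
#'   `lengths` (gene lengths, bp), `size_factors` (per-library scale
#'   factors, logged for reproducibility) and `delta_mcg` per gene.
#' @examples
#' cfg <- sim_config(seed = 5, n_genes = 12, chrom_len = 6e4, spikein_len = 2e3)
#' g <- simulate_genome(cfg)
#' truth <- simulate_methylome(g, cfg)
#' cm <- simulate_expression(g, truth, apply_knockdown(truth, 0.15), cfg)
#' dim(cm$counts)
#' @export
simulate_expression <- function(genome, truth_control, truth_kd, config) {
  stopifnot(inherits(genome, "sim_genome"),
            inherits(truth_control, "true_methylome"),
            inherits(truth_kd, "true_methylome"))
  if (config$n_reps_per_group < 2L)
    stop("`n_reps_per_group` must be at least 2")
  gene_ids <- genome$genes$gene_id
  ng <- length(gene_ids)
  reps <- config$n_reps_per_group
  delta <- truth_kd$genes$true_level - truth_control$genes$true_level
  delta[is.na(delta)] <- 0
  names(delta) <- gene_ids

  sf <- with_seed(stream_seed(config$seed, "size_factors"),
                  exp(rnorm(2L * reps, 0, 0.15)))
  lib_names <- c(sprintf("control_%d", seq_len(reps)),
                 sprintf("kd_%d", seq_len(reps)))
  groups <- factor(rep(c("control", "kd"), each = reps),
                   levels = c("control", "kd"))

  counts <- with_seed(stream_seed(config$seed, "expression"), {
    base <- 2 ^ runif(ng, config$nb_mean_log_range[1],
                      config$nb_mean_log_range[2])
    mu_kd <- base * 2 ^ (config$coupling_effect * delta)
    mu <- cbind(matrix(base, ng, reps), matrix(mu_kd, ng, reps))
    mu <- sweep(mu, 2L, sf, `*`)
    draw <- if (config$nb_dispersion > 0)
      rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion)
    else rpois(length(mu), mu)
    matrix(as.integer(draw), ng, 2L * reps,
           dimnames = list(gene_ids, lib_names))
  })

  structure(list(counts = counts, groups = groups,
                 lengths = stats::setNames(GenomicRanges::width(genome$genes),
                                           gene_ids),
                 size_factors = stats::setNames(sf, lib_names),
                 delta_mcg = delta),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts),
      "libraries (", sum(x$groups == "control"), "control /",
      sum(x$groups == "kd"), "kd )\n")
  invisible(x)
}
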