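#' Simulate a ground-truth CpG methylome
#'
#' Assigns every CpG dyad of a simulated genome a true methylation level in
#' `[0, 1]`, shared by both strands of the dyad (the signature of
#' maintenance-methyltransferase activity). Genes are assigned to a
#' methylated / unmethylated class by a Bernoulli draw with probability
#' `frac_methylated_genes`; dyads in methylated-class genes draw their level
#' from `Beta(meth_level_dist)`, dyads in unmethylated-class genes sit at
#' `unmeth_level`, TE dyads at `te_level`, intergenic dyads at
#' `intergenic_level`, and the spike-in contig is exactly 0 everywhere.
#' Compartment precedence for dyads under overlapping annotation is
#' gene > TE > intergenic.
#'
#' @param genome a [simulate_genome()] result.
#' @param config the [sim_config()] used to build it.
#' @return An object of class `true_methylome`: list with `dyads` (data.frame
#'   `chrom`, `pos` of the plus-strand C, per-strand 3-mer contexts,
#'   `compartment`, `gene_id`, true `level`) and `genes` (data.frame
#'   `gene_id`, ground-truth `class`, `true_level` mean over the gene's
#'   dyads).
#' @examples
#' cfg <- sim_config(seed = 2, n_genes = 8, chrom_len = 4e4, spikein_len = 5e3)
#' truth <- simulate_methylome(simulate_genome(cfg), cfg)
#' table(truth$genes$class)
#' @export
simulate_methylome <- function(genome, config) {
  stopifnot(inherits(genome, "sim_genome"))
  dyads <- find_dyads(genome$seqs)
  dgr <- GenomicRanges::GRanges(dyads$chrom,
                                IRanges::IRanges(dyads$pos, width = 1L))

  dyads$compartment <- "intergenic"
  dyads$compartment[dyads$chrom == genome$spikein] <- "spikein"
  dyads$gene_id <- NA_character_
  if (length(genome$tes)) {
    hit <- GenomicRanges::findOverlaps(dgr, genome$tes, select = "first")
    dyads$compartment[!is.na(hit) & dyads$compartment == "intergenic"] <- "te"
  }
  if (length(genome$genes)) {
    hit <- GenomicRanges::findOverlaps(dgr, genome$genes, select = "first")
    in_gene <- !is.na(hit)
    dyads$compartment[in_gene] <- "genic"
    dyads$gene_id[in_gene] <- genome$genes$gene_id[hit[in_gene]]
  }

  with_seed(stream_seed(config$seed, "methylome"), {
    gene_ids <- genome$genes$gene_id
    cls <- if (length(gene_ids))
      ifelse(rbinom(length(gene_ids), 1L, config$frac_methylated_genes) == 1L,
             "methylated", "unmethylated") else character(0)
    names(cls) <- gene_ids

    lvl <- numeric(nrow(dyads))
    lvl[dyads$compartment == "te"] <- config$te_level
    lvl[dyads$compartment == "intergenic"] <- config$intergenic_level
    lvl[dyads$compartment == "spikein"] <- 0
    gidx <- which(dyads$compartment == "genic")
    if (length(gidx)) {
      meth <- cls[dyads$gene_id[gidx]] == "methylated"
      lvl[gidx[!meth]] <- config$unmeth_level
      lvl[gidx[meth]] <- rbeta(sum(meth), config$meth_level_dist[1],
                               config$meth_level_dist[2])
    }
    dyads$level <- lvl

    gene_mean <- if (length(gidx))
      tapply(dyads$level[gidx], dyads$gene_id[gidx], mean)
    else stats::setNames(numeric(0), character(0))
    genes <- data.frame(
      gene_id = gene_ids,
      class = unname(cls),
      true_level = unname(ifelse(gene_ids %in% names(gene_mean),
                                 gene_mean[gene_ids], NA_real_)),
      stringsAsFactors = FALSE
    )
    structure(list(dyads = dyads, genes = genes), class = "true_methylome")
  })
}

#' @export
print.true_methylome <- function(x, ...) {
  cat("true_methylome:", nrow(x$dyads), "CpG dyads;",
      sum(x$genes$class == "methylated"), "/", nrow(x$genes),
      "genes in the methylated class\n")
  invisible(x)
}

# Locate CG dyads and their per-strand 3-mer contexts in a set of contig
# sequences. `pos` is the 1-based position of the plus-strand C.
find_dyads <- function(seqs) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  out <- lapply(names(seqs), function(ch) {
    s <- seqs[[ch]]
    m <- gregexpr("CG", s, fixed = TRUE)[[1]]
    if (m[1] == -1L) return(NULL)
    pos <- as.integer(m)
    nxt <- substring(s, pos + 2L, pos + 2L)      # base after the G
    prv <- substring(s, pos - 1L, pos - 1L)      # base before the C
    data.frame(
      chrom = ch, pos = pos,
      context_plus = paste0("CG", ifelse(nxt == "", "N", nxt)),
      context_minus = paste0("CG", ifelse(prv == "", "N",
                                          unname(comp[prv]))),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(chrom = character(0), pos = integer(0),
                      context_plus = character(0),
                      context_minus = character(0))
  out
}

#' Dilute a methylome by a cell-mixture knockdown
#'
#' Models passive loss of maintenance methylation: a fraction `f` of cells
#' retains the wild-type methylome while the remaining `1 - f` is fully
#' demethylated, so every site's population-average level is multiplied
#' by `f`.
#'
#' @param truth a [simulate_methylome()] result.
#' @param f retained fraction in `[0, 1]`.
#' @return A `true_methylome` with all dyad levels (and gene mean levels)
#'   scaled by `f`; ground-truth gene classes are unchanged.
#' @examples
#' cfg <- sim_config(seed = 3, n_genes = 5, chrom_len = 3e4, spikein_len = 2e3)
#' truth <- simulate_methylome(simulate_genome(cfg), cfg)
#' kd <- apply_knockdown(truth, 0.15)
#' max(kd$dyads$level) <= 0.15 * max(truth$dyads$level) + 1e-12
#' @export
apply_knockdown <- function(truth, f) {
  stopifnot(inherits(truth, "true_methylome"))
  stopifnot_proportion(f, "f")
  truth$dyads$level <- truth$dyads$level * f
  truth$genes$true_level <- truth$genes$true_level * f
  truth
}

#' Simulate an allc-style cytosine count table from a true methylome
#'
#' Observation model: per strand of each dyad, total reads are
#' `Poisson(depth_mean)` and methylated reads are `Binomial(n, pi)` with
#' `pi = level + (1 - level) * nonconversion_rate`; the two strands are
#' sampled independently.
#'
#' @param truth a [simulate_methylome()] (optionally [apply_knockdown()])
#'   result.
#' @param config the [sim_config()].
#' @param condition label choosing an independent RNG stream (`"control"`,
#'   `"kd"`, or anything else for a generic stream); lets paired conditions
#'   share a truth without sharing sampling noise.
#' @param shuffle_minus if `TRUE`, minus-strand reads are drawn from a
#'   permutation of the dyad levels rather than the dyad's own level. This
#'   is a null model that destroys strand symmetry while preserving the
#'   marginal level distribution; useful for calibrating symmetry
#'   statistics.
#' @return A data.frame in allc layout: `chrom`, `pos` (1-based), `strand`,
#'   `context`, `mc`, `n`, sorted by contig and position.
#' @examples
#' cfg <- sim_config(seed = 4, n_genes = 5, chrom_len = 3e4, spikein_len = 2e3)
#' truth <- simulate_methylome(simulate_genome(cfg), cfg)
#' head(simulate_site_counts(truth, cfg))
#' @export
simulate_site_counts <- function(truth, config, condition = "control",
                                 shuffle_minus = FALSE) {
  stopifnot(inherits(truth, "true_methylome"))
  if (config$depth_mean <= 0) stop("`depth_mean` must be positive")
  kind <- switch(condition, control = "counts_control", kd = "counts_kd",
                 "counts")
  d <- truth$dyads
  nd <- nrow(d)
  with_seed(stream_seed(config$seed, kind), {
    lev_minus <- if (shuffle_minus && nd > 1L) sample(d$level) else d$level
    n_plus <- rpois(nd, config$depth_mean)
    n_minus <- rpois(nd, config$depth_mean)
    pi_plus <- d$level + (1 - d$level) * config$nonconversion_rate
    pi_minus <- lev_minus + (1 - lev_minus) * config$nonconversion_rate
    mc_plus <- rbinom(nd, n_plus, pi_plus)
    mc_minus <- rbinom(nd, n_minus, pi_minus)
    out <- data.frame(
      chrom = rep(d$chrom, 2L),
      pos = c(d$pos, d$pos + 1L),
      strand = rep(c("+", "-"), each = nd),
      context = c(d$context_plus, d$context_minus),
      mc = c(mc_plus, mc_minus),
      n = c(n_plus, n_minus),
      stringsAsFactors = FALSE
    )
    out[order(out$chrom, out$pos), , drop = FALSE]
  })
}
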