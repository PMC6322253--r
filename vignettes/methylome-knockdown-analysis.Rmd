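---
title: "Methods: gene-body methylation, knockdown simulation and methylation-expression association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-body methylation, knockdown simulation and methylation-expression association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methex)
```

# Scope and model

`methex` analyses per-cytosine bisulfite count data from genomes with
sparse, bimodal gene-body CG methylation — the situation typical of
hemimetabolous insects — and asks the three questions such studies turn
on: how much CG methylation there is and where; which genes are
CG-methylated; and whether methylation (or its loss after a maintenance
methyltransferase knockdown) is associated with gene or TE expression.

The data model is the allc table: one row per cytosine with chromosome,
1-based position, strand, 3-mer context, methylated read count `mc` and
total read count `n`. Every methylation quantity in the package is a
*weighted* level,

$$ m = \frac{\sum_i mc_i}{\sum_i n_i}, $$

i.e. a read-pooled estimate rather than a mean of per-site ratios, so
deep sites carry proportionally more information and the statistic is
invariant to how the site stream is split or ordered. A level over a set
with zero total reads is *undefined* and represented as `NA`, never as 0;
undefined levels are excluded from every downstream average.

Assumptions worth stating explicitly:

* reads are independent Bernoulli draws per site given the cell-population
  methylation level — no read-level dependence, no mapping bias;
* the non-conversion error acts uniformly: an unmethylated cytosine reads
  out methylated with probability equal to the spike-in rate;
* gene extent is the start-to-stop-codon interval of the annotation, and
  annotation coordinates are 1-based inclusive inside the package (BED
  input is converted on read).

# The methylated-gene caller

Per gene, reads over all its CG sites are pooled and tested against a
background rate $p_0$ with a one-sided binomial test,
$p = P[\mathrm{Bin}(\Sigma n, p_0) \ge \Sigma mc]$, followed by
Benjamini–Hochberg correction; `q < 0.05` calls the gene CG-methylated.
Choices behind that sentence:

* **Binomial unit.** The test aggregates *reads* over a gene, matching the
  read-and-site phrasing of the coverage thresholds; per-site calling was
  rejected because single insect genes rarely offer enough per-site depth
  at ~10x coverage.
* **Coverage thresholds.** A gene is *determinate* when it has at least 20
  total reads AND at least 20 covered CG sites (defaults `min_reads`,
  `min_sites`). Indeterminate genes are excluded from the BH multiplicity
  set entirely, so underpowered genes neither receive calls nor dilute the
  FDR control of those that can be called.
* **Background $p_0$.** The weighted level over all coding sequence,
  floored at the estimated non-conversion rate so a fully unmethylated
  background cannot degenerate the test to $p_0 = 0$.
* **False-negative drop rule.** After calling, any "unmethylated" gene
  whose level exceeds the lowest level among methylated genes is
  re-labelled `dropped` and excluded downstream: with few significant
  sites a highly methylated gene can fail the test while plainly not being
  unmethylated. The rule never touches methylated calls.
* **Overlapping genes.** Sites inside two overlapping genes count toward
  both (the symmetric choice; annotation overlap is rare).
* **Cross-condition comparison.** `compare_status()` partitions genes into
  DMG (determinate in both conditions, status differs), SMG (methylated in
  both), UMG (unmethylated in both), everything else unclassified, and
  exports the per-gene level change so level-based definitions of
  differential methylation can also be applied. For knockdown-vs-control
  comparisons the package classifies *both* conditions against the
  control-derived $p_0$: under a uniform cell-mixture dilution a
  per-condition background would preserve each gene's *relative*
  enrichment and no gene would ever change status, whereas the common
  reference makes a status change mean "this gene lost its wild-type
  methylation", which is the question actually asked of a knockdown.

# Metaplots

`meta_profile()` splits each feature body into `k = 20` windows
proportional to sequence length and each 1-kb flank into `k` equal
windows. The body remainder (`length mod k`) is spread one base at a time
over the first windows, so windows tile the body exactly; minus-strand
features reverse the window numbering so window 1 is always biologically
upstream. Flanks use the same `k` as the body — the natural reading of
"20 windows" applying to all three segments — and `k` is configurable.
Window levels are pooled (read-weighted) across features by default,
consistent with the weighted-level convention; `pooled = FALSE` averages
per-feature levels instead, weighting each feature equally, for checking
that deep features do not dominate a profile. Features shorter than `k`
bp are skipped and counted rather than windowed at sub-base resolution.

# Dyad symmetry

A CpG dyad pairs the plus-strand C at position `p` with the minus-strand
C at `p + 1`. `dyad_symmetry_summary()` keeps dyads with at least
`min_cov = 3` reads on *each* strand (configurable; the per-site density
and symmetry displays are meaningless at 1-2 reads), computes per-strand
levels and their Pearson correlation, and returns both per-site and
per-dyad level histograms — the density convention differs between
studies, so both are produced. Dyads covered on one strand only
("orphans") are excluded from symmetry analysis but remain in pooled
levels.

# Expression and association

FPKM is `count * 1e9 / (length_bp * library_total)`; CPM filtering
retains genes with CPM ≥ 1 in ≥ 2 libraries; log2 fold-changes are ratios
of group-mean FPKM with half the smallest nonzero group mean substituted
for zeros. TE records of one family are collapsed when overlapping or
book-ended; families are ranked by the number of collapsed loci ≥ 500 bp;
TE expression is reported both as RPKM (with the per-kilobase term — the
name promises it) and as plain reads-per-million, and both per locus and
pooled per family, because conventions differ. DE significance is
consumed from a table (`load_deg_table()`, DEG iff FDR < 0.05); the
packaged `de_standin_test()` (edgeR classic exact NB test, TMM, BH) is a
labelled substitute for simulation studies only.

The association suite works on log2-transformed expression (same
pseudo-value policy — the analysis scale is not dictated by the FPKM
unit): decile bins are rank-based cuts of methylated genes with stable
gene-id tie-breaking and sizes differing by at most one, with t-based 95%
confidence intervals per bin; the continuous analysis is OLS of log2
expression on weighted mCG level over expressed genes, with a Bonferroni
flag at `0.05 / m` where `m` is the number of regressions in the
invocation's family (a panel across tissues or species sets `m`
accordingly); the delta-delta analysis pairs `level_kd - level_ctrl` with
log2FC on a fixed grid and reports Spearman's rho, which is robust to the
heavy tails of fold-changes.

# The synthetic-data generator

The generator produces the statistical structure the analysis assumes,
with defaults set to the study conditions it emulates:

| parameter | default | meaning |
|---|---|---|
| `frac_methylated_genes` | 0.4 | ~40% of genes gene-body methylated |
| `meth_level_dist` | Beta(8, 2) | per-dyad levels in methylated genes, mean 0.8 |
| `unmeth_level` | 0 | unmethylated-class genes |
| `te_level`, `intergenic_level` | 0.4, 0.1 | TEs moderately methylated, background low |
| `nonconversion_rate` | 5e-4 | ~0.05% bisulfite non-conversion |
| `depth_mean` | 10 reads/site/strand | ~10x mapped coverage |
| `retained_fraction` | 0.15 | knockdown: 15% of cells keep the wild-type methylome |
| `n_reps_per_group` | 3 | RNA-seq biological replicates |
| `nb_dispersion` | 0.1 | squared biological CV of counts |
| `coupling_effect` | 0 | log2FC per unit change of gene mCG |

Structure: genes are placed without overlap, at least `2 * flank_len`
from contig ends (so metaplot flanks are always defined); TEs fill
intergenic space; one spike-in contig is exactly unmethylated everywhere,
so its only methylated reads are non-conversion failures. Every CpG dyad
carries one true level shared by both strands; the knockdown multiplies
every level by the retained fraction `f` — the direct formalisation of
passive dilution in a cell mixture where `1 - f` of cells are fully
demethylated. Counts are `n ~ Poisson(depth_mean)` per strand and
`mc ~ Bin(n, level + (1 - level) * nonconversion)`, strands independent.
Expression is negative-binomial with per-library lognormal size factors;
the knockdown group mean is multiplied by
`2^(coupling_effect * delta_mCG)`, so `coupling_effect = 0` is an exact
null for every association statistic and positive/negative values plant a
signed alternative for power studies. Each output kind draws from its own
RNG stream derived from the master seed, so enlarging the TE annotation
cannot perturb gene-level draws, and identical configurations give
byte-identical files.

`simulate_site_counts(..., shuffle_minus = TRUE)` permutes the
minus-strand levels across dyads: a null model that preserves the
marginal level distribution while destroying strand symmetry, used to
calibrate the symmetry correlation.

What the generator deliberately does **not** emulate: read-level
sequencing (no FASTQ, no mapping bias or clonal reads), coverage
autocorrelation along the genome (depth is i.i.d.), CHG/CHH methylation
(only CG sites are emitted, the analysed context), sub-gene methylation
structure (a gene's dyads are i.i.d. given its class) and compositional
library effects beyond size factors. Passing tests on this generator
therefore demonstrates correctness of the statistics under the stated
model, not robustness to alignment artefacts or covariate structure in
real libraries.

# Numerical choices and degenerate inputs

* Undefined levels are `NA`, distinct from 0, everywhere.
* `p0` must lie strictly inside (0, 1); the floor (non-conversion rate)
  guarantees that.
* A gene with no covered sites is `indeterminate`, never an error.
* Dyad correlation with fewer than two qualifying dyads or zero variance
  is `NA` with `correlation_defined = FALSE` and a warning.
* The rank test with all values tied returns `p = 1` with a warning.
* Zero-variance mCG makes the regression slope undefined (flagged), not
  an exception; an all-zero expression row is left unscaled and flagged in
  the heatmap matrix.
* Quantile bins break level ties by gene id, so binning is deterministic.
* Flank windows extending past a contig end are truncated, possibly to
  empty windows that simply collect no reads.

# Interfaces

The package is library-shaped, like most Bioconductor methylation tooling:
the exported functions compose into scripts, and `scripts/acceptance.R`
is the packaged end-to-end driver. No shell subcommand layer is provided;
readers coming from pipeline tools should treat `sim_config()` +
`write_sim_outputs()` as `sim`, `compartment_levels()` /
`dyad_symmetry_summary()` / `estimate_nonconversion()` as the level
summaries, `classify_genes()` + `compare_status()` as the caller, and the
association functions as the final analyses.

# Problem sizes in the shipped checks

The test suite and acceptance script run the full pipeline at desk scale,
chosen so that every stochastic check has comfortable statistical margin:
genomes of 1-2 contigs of 80-700 kb (roughly 5e3-9e4 CpG dyads), 40-500
genes, 20x depth for recovery/symmetry checks, 2000-gene fixtures for
caller calibration and power, 50 replicate pipelines for regression
calibration, and 100 replicate spike-ins for CI coverage. The published
insect datasets the method family targets are two orders of magnitude
larger; all statistics here are either exact or scale-free, so size
affects only Monte-Carlo margin.

# Known limitations

* The caller's FDR control is across genes within one condition; the
  DMG/SMG/UMG partition inherits whatever error the two call sets carry
  and applies no joint correction.
* The common-background convention for knockdown comparison presumes the
  control is the biologically meaningful reference; comparing two
  arbitrary tissues may warrant per-condition backgrounds
  (`classify_genes()` accepts any `p0`).
* FPKM fold-changes carry compositional bias when a large gene class
  changes in one direction; the stand-in DE test uses TMM-normalised
  counts and does not share it, but the descriptive log2FC column does.
* The binomial test treats reads within a gene as exchangeable; true
  within-gene heterogeneity (e.g. methylated exons only) is averaged
  away, which is also why the false-negative drop rule exists.
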