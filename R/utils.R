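# Internal helpers shared across modules.

# Independent RNG streams derived from one master seed, so that draws for one
# output kind (genome, methylome, counts, ...) do not shift when another kind
# is added or resized. Sub-seeds stay below 2^31 - 1.
.stream_offsets <- c(
  genome = 11L, genes = 23L, tes = 37L, methylome = 53L,
  counts_control = 71L, counts_kd = 89L, counts = 97L,
  expression = 113L, size_factors = 131L, misc = 149L
)

stream_seed <- function(seed, kind) {
  off <- .stream_offsets[[kind]]
  if (is.null(off)) stop("unknown RNG stream kind: ", kind)
  s <- abs(as.integer(seed)) %% 16777000L
  (s * 127L + off) %% 2147483647L
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the global
# RNG state is restored afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

stopifnot_proportion <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop("`", name, "` must be a single proportion in [0, 1]", call. = FALSE)
  invisible(x)
}

# Weighted methylation level of a pooled count set: sum(mc) / sum(n).
# Returns NA_real_ (undefined, distinct from 0) when total coverage is zero.
wml <- function(mc, n) {
  tot <- sum(as.numeric(n))
  if (tot == 0) return(NA_real_)
  sum(as.numeric(mc)) / tot
}

# log2 with the pseudo-value policy used throughout: half the smallest
# nonzero value is added to zeros before taking logs. All-zero input gets a
# pseudo-value of 1 (log2 -> 0) so downstream summaries stay finite.
log2_pseudo <- function(x) {
  pos <- x[x > 0]
  p <- if (length(pos)) min(pos) / 2 else 1
  log2(ifelse(x == 0, p, x))
}

# Sites table -> GRanges of width-1 positions (allc positions are 1-based).
sites_granges <- function(sites) {
  GenomicRanges::GRanges(sites$chrom, IRanges::IRanges(sites$pos, width = 1L))
}

is_cg_context <- function(context) startsWith(as.character(context), "CG")
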