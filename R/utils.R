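#' @import data.table
#' @importFrom stats dbinom dhyper dpois rbinom rpois runif setNames rnbinom
#' @importFrom utils head tail
NULL

# silence R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  ".", ".N", ".SD", ".BY", "chrom", "pos", "line", "depth", "alt_count",
  "ref_count", "gq", "freq", "status", "win", "start", "end", "het",
  "category", "count", "S", "state", "n_snps", "J", "grp", "ok",
  "n_alleles", "all_ok", "g1_ref", "g1_alt", "g2_ref", "g2_alt", "n_ref",
  "n_alt", "alt_line", "ref_line", "n_missing", "n_lines", "incomplete",
  "gene_id", "type", "len", "effect", "line_i", "line_j", "grouping",
  "fst", "class", "mean_het", "dist_to_shared", "shared_bp", "group",
  "chrom_class", "mean_posterior", "p_selection", "theta_w", "wstart",
  "wend", "gf1", "gf2", "experiment_specific", "single_line_discordant"
))

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value for the table `[[a, b], [c, d]]`, computed by
#' summing hypergeometric point probabilities not exceeding that of the
#' observed table. Vectorised over the hypergeometric support, so tables
#' with margins in the hundreds of thousands (e.g. genome-wide site counts)
#' are handled in milliseconds.
#'
#' @param a,b,c,d Non-negative integer cell counts, first row `a, b`,
#'   second row `c, d`.
#' @return List with `p.value` (two-sided) and `odds.ratio` (sample odds
#'   ratio `ad/bc`, `Inf`/`NaN` for degenerate cells).
#' @examples
#' fisher_exact_2x2(2, 2, 22, 0)$p.value
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  stopifnot(length(a) == 1, a >= 0, b >= 0, c >= 0, d >= 0)
  m <- a + b      # row 1 total
  n <- c + d      # row 2 total
  k <- a + c      # column 1 total
  if ((m == 0 && n == 0) || k + b + d == 0) {
    return(list(p.value = 1, odds.ratio = NaN))
  }
  lo <- max(0L, k - n)
  hi <- min(m, k)
  xs <- lo:hi
  ps <- dhyper(xs, m, n, k)
  p0 <- dhyper(a, m, n, k)
  # relative tolerance guards against FP noise in the tail sums
  p <- sum(ps[ps <= p0 * (1 + 1e-7)])
  or <- (a * d) / (b * c)
  list(p.value = min(1, p), odds.ratio = or)
}

#' Tile a chromosome into sliding windows
#'
#' @param chrom_length Chromosome length in bp.
#' @param size_bp Window size in bp.
#' @param step_bp Step between window starts (`step_bp <= size_bp`).
#' @return data.table with `start`, `end` (0-based, half-open). The last
#'   window is clipped at `chrom_length`.
#' @export
tile_windows <- function(chrom_length, size_bp, step_bp = size_bp) {
  stopifnot(size_bp > 0, step_bp > 0, step_bp <= size_bp,
            chrom_length > 0)
  starts <- seq(0, max(0, chrom_length - 1), by = step_bp)
  starts <- starts[starts < chrom_length]
  dt <- data.table(start = as.integer(starts),
                   end = as.integer(pmin(starts + size_bp, chrom_length)))
  dt[end > start]
}

# internal: derive a child RNG seed below 2^31 from a base seed and a tag
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed))
  as.integer((as.numeric(seed) * 7919 + tag * 104729) %% 2147483647L)
}
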