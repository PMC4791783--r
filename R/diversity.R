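#' Sliding-window specification
#'
#' @param size_bp Window size in bp (default 10 kb, the diversity-scan
#'   default; use 100 kb for heterozygosity profiles).
#' @param step_bp Step between window starts (default 10 kb; `step = size`
#'   tiles the chromosome without overlap).
#' @param min_snps Minimum SNPs for a window to report statistics
#'   (default 1; windows below emit NA).
#' @return Object of class `window_spec`.
#' @export
window_spec <- function(size_bp = 10000, step_bp = 10000, min_snps = 1) {
  stopifnot(size_bp > 0, step_bp > 0, step_bp <= size_bp, min_snps >= 0)
  structure(list(size_bp = size_bp, step_bp = step_bp,
                 min_snps = min_snps), class = "window_spec")
}

#' Tajima's D normalising constants
#'
#' The classical constants for sample size `n` chromosomes:
#' `a1 = sum 1/i`, `a2 = sum 1/i^2` (i = 1..n-1), `b1 = (n+1)/(3(n-1))`,
#' `b2 = 2(n^2+n+3)/(9n(n-1))`, `c1 = b1 - 1/a1`,
#' `c2 = b2 - (n+2)/(a1 n) + a2/a1^2`, `e1 = c1/a1`, `e2 = c2/(a1^2+a2)`.
#'
#' @param n Number of sampled chromosomes (>= 2).
#' @return Named list of the eight constants.
#' @export
tajima_constants <- function(n) {
  stopifnot(n >= 2)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = e1, e2 = e2)
}

#' Windowed diversity statistics from pooled frequencies
#'
#' Per sliding window and line: segregating sites `S`, mean expected
#' heterozygosity `H = mean(2 p (1-p))`, nucleotide diversity
#' `pi = sum 2 p (1-p) n/(n-1)`, Watterson's `theta_W = S / a1` and
#' Tajima's `D = (pi - theta_W) / sqrt(e1 S + e2 S (S-1))` with the
#' classical constants for `n` chromosomes. Frequencies are the pooled
#' read-derived allele fractions; windows with fewer than `min_snps`
#' segregating sites report NA statistics (`D` additionally requires the
#' variance term to be positive).
#'
#' @param counts data.table with `chrom, pos, line, freq` (alt fraction;
#'   from [filter_variants()] or [sample_pool_counts()]).
#' @param spec A [window_spec()].
#' @param n Sample size in chromosomes (default 200 = 100 diploids).
#' @param chrom_length Chromosome length for the window tiling; default
#'   extends to the last SNP.
#' @param per_bp Divide `pi` and `theta_W` by window size (default FALSE:
#'   per-window sums).
#' @return data.table `chrom, line, start, end, S, H, pi, theta_w, D`.
#' @export
window_diversity <- function(counts, spec = window_spec(), n = 200,
                             chrom_length = NULL, per_bp = FALSE) {
  if (n < 2) stop("n must be at least 2")
  dt <- as.data.table(counts)
  if (!nrow(dt)) return(data.table())
  k <- tajima_constants(n)
  out <- dt[, {
    len <- if (is.null(chrom_length)) max(pos) + 1L else chrom_length
    wins <- tile_windows(len, spec$size_bp, spec$step_bp)
    res <- lapply(seq_len(nrow(wins)), function(w) {
      x <- freq[pos >= wins$start[w] & pos < wins$end[w]]
      x <- x[!is.na(x)]
      seg <- x > 0 & x < 1
      S <- sum(seg)
      # H averages over every observed site: sites driven to fixation
      # contribute 0 (the sweep signature); a window with no sites at
      # all is missing
      H <- if (length(x)) mean(2 * x * (1 - x)) else NA_real_
      if (S < max(spec$min_snps, 1L)) {
        return(data.table(start = wins$start[w], end = wins$end[w],
                          S = S, H = H, pi = NA_real_,
                          theta_w = NA_real_, D = NA_real_))
      }
      h <- 2 * x[seg] * (1 - x[seg])
      pi <- sum(h) * n / (n - 1)
      th <- S / k$a1
      varD <- k$e1 * S + k$e2 * S * (S - 1)
      D <- if (varD > 0) (pi - th) / sqrt(varD) else NA_real_
      scale <- if (per_bp) wins$end[w] - wins$start[w] else 1
      data.table(start = wins$start[w], end = wins$end[w], S = S,
                 H = H, pi = pi / scale, theta_w = th / scale, D = D)
    })
    rbindlist(res)
  }, by = .(chrom, line)]
  out[]
}

#' Per-SNP FST between two pools
#'
#' Classical two-population estimator
#' `FST = (H_T - H_S) / H_T` with `H_S = (2 p_i q_i + 2 p_j q_j)/2` and
#' `H_T = 2 p_bar q_bar`, `p_bar = (p_i + p_j)/2`. Sites monomorphic in
#' both pools (`H_T = 0`) return NA and are skipped in summaries.
#'
#' @param p_i,p_j Allele frequencies in the two pools (vectors).
#' @return data.table `p_i, p_j, H_T, H_S, fst`.
#' @export
snp_fst <- function(p_i, p_j) {
  stopifnot(length(p_i) == length(p_j),
            all(p_i >= 0 & p_i <= 1, na.rm = TRUE),
            all(p_j >= 0 & p_j <= 1, na.rm = TRUE))
  pbar <- (p_i + p_j) / 2
  ht <- 2 * pbar * (1 - pbar)
  hs <- (2 * p_i * (1 - p_i) + 2 * p_j * (1 - p_j)) / 2
  fst <- ifelse(ht > 0, (ht - hs) / ht, NA_real_)
  data.table(p_i = p_i, p_j = p_j, H_T = ht, H_S = hs, fst = fst)
}

#' Mean pairwise FST within and between line sets
#'
#' For every line pair, averages per-SNP FST over SNPs; pair means are then
#' averaged within set A, within set B, and across sets.
#'
#' @param freqs Numeric matrix, lines in rows (rownames = line names),
#'   sites in columns.
#' @param set_a,set_b Character vectors of line names.
#' @return List with `within_a`, `within_b`, `between`, and the per-pair
#'   table `pairs`.
#' @export
mean_pairwise_fst <- function(freqs, set_a, set_b) {
  if (!length(set_a) || !length(set_b)) stop("empty line set")
  stopifnot(all(c(set_a, set_b) %in% rownames(freqs)))
  pair_mean <- function(a, b) {
    f <- snp_fst(freqs[a, ], freqs[b, ])$fst
    mean(f, na.rm = TRUE)
  }
  pairs_of <- function(set) {
    if (length(set) < 2) return(NULL)
    cmb <- utils::combn(set, 2)
    data.table(line_i = cmb[1, ], line_j = cmb[2, ])
  }
  wa <- pairs_of(set_a)
  wb <- pairs_of(set_b)
  ab <- data.table(expand.grid(line_i = set_a, line_j = set_b,
                               stringsAsFactors = FALSE))
  tab <- rbind(
    if (!is.null(wa)) wa[, .(line_i, line_j, grouping = "within_a")],
    if (!is.null(wb)) wb[, .(line_i, line_j, grouping = "within_b")],
    ab[, .(line_i, line_j, grouping = "between")])
  tab[, fst := mapply(pair_mean, line_i, line_j)]
  list(within_a = if (!is.null(wa)) mean(tab[grouping == "within_a", fst])
       else NA_real_,
       within_b = if (!is.null(wb)) mean(tab[grouping == "within_b", fst])
       else NA_real_,
       between = mean(tab[grouping == "between", fst]),
       pairs = tab[])
}
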