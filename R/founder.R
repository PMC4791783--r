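#' Founder haplotype panel
#'
#' Container for a panel of founder haplotypes over biallelic sites on one
#' chromosome, the seed of all simulations in the package. Alleles are coded
#' 0 (reference/ancestral) and 1 (derived). Positions are 0-based.
#'
#' @param chrom Chromosome label.
#' @param length_bp Chromosome length in bp (positive).
#' @param positions Strictly increasing integer vector of site positions in
#'   `[0, length_bp)`.
#' @param alleles Integer matrix over `{0, 1}`, haplotypes in rows, sites in
#'   columns.
#' @param allow_monomorphic Keep non-segregating columns instead of erroring.
#' @return Object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(chrom, length_bp, positions, alleles,
                            allow_monomorphic = FALSE) {
  positions <- as.integer(positions)
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  stopifnot(length_bp > 0, nrow(alleles) >= 1,
            ncol(alleles) == length(positions))
  if (length(positions)) {
    if (any(positions < 0L) || any(positions >= length_bp))
      stop("positions must lie in [0, length_bp)")
    if (any(diff(positions) <= 0L))
      stop("positions must be strictly increasing (no duplicates)")
    if (!all(alleles %in% c(0L, 1L)))
      stop("alleles must be 0/1")
    if (!allow_monomorphic) {
      cs <- colSums(alleles)
      if (any(cs == 0L | cs == nrow(alleles)))
        stop("panel contains non-segregating sites; ",
             "pass allow_monomorphic = TRUE to keep them")
    }
  }
  structure(list(chrom = chrom, length_bp = as.numeric(length_bp),
                 positions = positions, alleles = alleles,
                 n_haplotypes = nrow(alleles)),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat("haplotype_panel:", x$n_haplotypes, "haplotypes,",
      length(x$positions), "sites on", x$chrom,
      sprintf("(%.3g bp)\n", x$length_bp))
  invisible(x)
}

#' Derived-allele frequencies of a panel
#' @param panel A [haplotype_panel()].
#' @return Numeric vector of per-site derived frequencies.
#' @export
panel_freqs <- function(panel) {
  if (!length(panel$positions)) return(numeric(0))
  colMeans(panel$alleles)
}

#' Simulate a founder panel under the neutral frequency spectrum
#'
#' Generates `n_sites` independent biallelic sites whose derived-allele
#' counts `j` follow the standard neutral site-frequency spectrum
#' `P(j) proportional to 1/j`, `j = 1..n_haplotypes - 1`, at positions drawn
#' uniformly without replacement. This emulates a founder population drawn
#' from a large panel of inbred lines (haplotypes) at mutation-drift
#' equilibrium; sites carry no linkage disequilibrium by default.
#'
#' @param n_haplotypes Number of founder haplotypes (>= 2); default 205.
#' @param n_sites Number of segregating sites.
#' @param chrom_length Chromosome length in bp (must be >= n_sites).
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments including the seed.
#' @param chrom Chromosome label.
#' @param ld_blocks Optional integer. When given, haplotypes are built as
#'   mosaics copied block-wise from `ld_blocks` archetype haplotypes,
#'   introducing strong local linkage disequilibrium (for HMM stress tests).
#'   Default `NULL`: independent sites.
#' @return A [haplotype_panel()].
#' @export
gen_founder_panel <- function(n_haplotypes = 205, n_sites, chrom_length,
                              seed, chrom = "chrS", ld_blocks = NULL) {
  stopifnot(n_haplotypes >= 2, n_sites >= 0, chrom_length > 0)
  if (n_sites > chrom_length)
    stop("n_sites exceeds chrom_length: cannot place distinct positions")
  set.seed(derive_seed(seed, 1L))
  if (n_sites == 0) {
    return(haplotype_panel(chrom, chrom_length, integer(0),
                           matrix(integer(0), n_haplotypes, 0)))
  }
  positions <- sort(sample.int(chrom_length, n_sites)) - 1L
  jmax <- n_haplotypes - 1L
  counts <- sample.int(jmax, n_sites, replace = TRUE, prob = 1 / seq_len(jmax))
  alleles <- matrix(0L, n_haplotypes, n_sites)
  if (is.null(ld_blocks)) {
    for (s in seq_len(n_sites)) {
      alleles[sample.int(n_haplotypes, counts[s]), s] <- 1L
    }
  } else {
    stopifnot(ld_blocks >= 2)
    # archetype haplotypes carry the derived alleles; each founder copies
    # archetype identity in contiguous blocks => local LD, same margins
    arch <- matrix(0L, ld_blocks, n_sites)
    for (s in seq_len(n_sites)) {
      k <- max(1L, round(counts[s] / n_haplotypes * ld_blocks))
      arch[sample.int(ld_blocks, k), s] <- 1L
    }
    n_blocks <- max(1L, n_sites %/% 50L)
    bounds <- sort(unique(c(0L, sample.int(n_sites - 1L,
                                           min(n_blocks, n_sites - 1L)),
                            n_sites)))
    for (h in seq_len(n_haplotypes)) {
      for (b in seq_len(length(bounds) - 1L)) {
        idx <- (bounds[b] + 1L):bounds[b + 1L]
        alleles[h, idx] <- arch[sample.int(ld_blocks, 1L), idx]
      }
    }
  }
  haplotype_panel(chrom, chrom_length, positions, alleles,
                  allow_monomorphic = !is.null(ld_blocks))
}

#' Spike a hard or soft selective sweep into per-replicate frequencies
#'
#' Overwrites derived-allele frequencies inside a genomic region to emulate
#' a completed sweep. In `hard` mode a single replicate is driven to (near)
#' fixation for one haplotype's alleles: heterozygosity inside the region
#' collapses in that replicate only. In `soft` mode two or more replicates
#' fix the same standing haplotype in parallel, the signature expected when
#' selection acts on shared standing variation.
#'
#' @param freqs Numeric matrix of derived frequencies, replicates in rows,
#'   sites in columns.
#' @param positions Site positions (0-based), one per column of `freqs`.
#' @param region Numeric `c(start, end)`, 0-based half-open.
#' @param mode `"hard"` or `"soft"`.
#' @param replicate_ids Row indices (or rownames) of the swept replicates;
#'   exactly one for `hard`, at least two for `soft`.
#' @param panel Optional [haplotype_panel()] supplying the standing
#'   haplotype whose alleles are fixed; when `NULL` a random 0/1 haplotype
#'   is drawn.
#' @param carrier_freq Frequency the swept haplotype reaches (default 1).
#' @param seed Integer seed.
#' @return `freqs` with in-region rows replaced; sites outside the region
#'   are returned bit-identical.
#' @export
spike_sweep <- function(freqs, positions, region, mode = c("hard", "soft"),
                        replicate_ids, panel = NULL, carrier_freq = 1,
                        seed = 1) {
  mode <- match.arg(mode)
  freqs <- as.matrix(freqs)
  stopifnot(length(region) == 2, ncol(freqs) == length(positions),
            carrier_freq >= 0.99, carrier_freq <= 1)
  if (region[2] <= region[1]) stop("empty region")
  if (is.character(replicate_ids)) {
    replicate_ids <- match(replicate_ids, rownames(freqs))
  }
  if (any(is.na(replicate_ids)) || any(replicate_ids < 1) ||
      any(replicate_ids > nrow(freqs)))
    stop("unknown replicate id")
  if (mode == "hard" && length(replicate_ids) != 1)
    stop("hard mode requires exactly one replicate id")
  if (mode == "soft" && length(replicate_ids) < 2)
    stop("soft mode requires at least two replicate ids")
  inreg <- positions >= region[1] & positions < region[2]
  if (!any(inreg)) return(freqs)
  set.seed(derive_seed(seed, 2L))
  hap <- if (!is.null(panel)) {
    panel$alleles[sample.int(panel$n_haplotypes, 1L), inreg]
  } else {
    as.integer(runif(sum(inreg)) < 0.5)
  }
  target <- ifelse(hap == 1L, carrier_freq, 1 - carrier_freq)
  for (r in replicate_ids) freqs[r, inreg] <- target
  freqs
}

#' Pool sampling configuration
#'
#' Parameters of the pooled-sequencing read sampling model: a pool of
#' `pool_individuals` diploids sequenced to a mean per-site depth of
#' `mean_coverage`, with optional symmetric base-error rate.
#'
#' @param pool_individuals Number of diploid individuals in the pool.
#' @param mean_coverage Mean per-site sequencing depth (Poisson).
#' @param error_rate Per-read error probability in `[0, 0.01]`; an erroneous
#'   read reports the opposite allele, so the alternate-read probability at
#'   true frequency `p` is `p(1 - e) + (1 - p)e`.
#' @param seed Integer seed.
#' @return Object of class `pool_sampling_config`.
#' @export
pool_sampling_config <- function(pool_individuals = 100, mean_coverage = 35,
                                 error_rate = 0, seed = 1) {
  stopifnot(pool_individuals >= 1, mean_coverage >= 0,
            error_rate >= 0, error_rate <= 0.01)
  structure(list(pool_individuals = pool_individuals,
                 mean_coverage = mean_coverage,
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "pool_sampling_config")
}

#' Sample pooled read counts from true allele frequencies
#'
#' Emulates Pool-seq: per site, depth is Poisson with the configured mean
#' and the alternate read count is binomial in the (error-adjusted) true
#' frequency. With zero error the alternate fraction is an unbiased
#' estimator of the true frequency.
#'
#' @param true_freqs Numeric vector of true derived frequencies in `[0,1]`.
#' @param config A [pool_sampling_config()].
#' @param chrom Chromosome label for the output table.
#' @param positions Optional site positions (default `0:(n-1)`).
#' @param line Line label for the output table.
#' @return data.table with columns `chrom, pos, line, ref_count, alt_count,
#'   depth, gq, freq, missing` (sites with depth 0 are flagged missing and
#'   have `freq = NA`).
#' @export
sample_pool_counts <- function(true_freqs, config, chrom = "chrS",
                               positions = NULL, line = "L1") {
  stopifnot(inherits(config, "pool_sampling_config"),
            all(true_freqs >= 0 & true_freqs <= 1))
  if (config$mean_coverage < 0) stop("negative coverage parameter")
  n <- length(true_freqs)
  if (is.null(positions)) positions <- seq_len(n) - 1L
  set.seed(derive_seed(config$seed, 3L))
  depth <- rpois(n, config$mean_coverage)
  e <- config$error_rate
  p_read <- true_freqs * (1 - e) + (1 - true_freqs) * e
  alt <- rbinom(n, depth, p_read)
  data.table(chrom = chrom, pos = as.integer(positions), line = line,
             ref_count = as.integer(depth - alt), alt_count = as.integer(alt),
             depth = as.integer(depth),
             gq = ifelse(depth > 0, 99, 0),
             freq = ifelse(depth > 0, alt / depth, NA_real_),
             missing = depth == 0)
}

#' Simulate pooled count tables for a full replicated design
#'
#' Convenience generator for the standard six-line design: each line is
#' founded by resampling `2 * pool_individuals` haplotypes from the founder
#' panel (line-to-line drift), optional sweeps are spiked, and pooled read
#' counts are sampled per line.
#'
#' @param panel A [haplotype_panel()].
#' @param lines Character vector of line names.
#' @param config A [pool_sampling_config()].
#' @param sweeps Optional list of lists with fields `region`, `mode`,
#'   `replicate_ids` passed to [spike_sweep()].
#' @param seed Integer seed.
#' @return List with `counts` (rbind-ed per-line tables) and `true_freqs`
#'   (line x site matrix).
#' @export
gen_pool_experiment <- function(panel, lines = c("S1", "S2", "S3",
                                                 "C1", "C2", "C3"),
                                config = pool_sampling_config(),
                                sweeps = NULL, seed = 1) {
  nsite <- length(panel$positions)
  freqs <- matrix(0, length(lines), nsite,
                  dimnames = list(lines, NULL))
  set.seed(derive_seed(seed, 4L))
  nchr <- 2L * config$pool_individuals
  for (i in seq_along(lines)) {
    idx <- sample.int(panel$n_haplotypes, nchr, replace = TRUE)
    freqs[i, ] <- colMeans(panel$alleles[idx, , drop = FALSE])
  }
  if (!is.null(sweeps)) {
    for (k in seq_along(sweeps)) {
      sw <- sweeps[[k]]
      freqs <- spike_sweep(freqs, panel$positions, sw$region, sw$mode,
                           sw$replicate_ids, panel = panel,
                           seed = derive_seed(seed, 100L + k))
    }
  }
  tabs <- lapply(seq_along(lines), function(i) {
    cfg <- config
    cfg$seed <- derive_seed(seed, 200L + i)
    sample_pool_counts(freqs[i, ], cfg, chrom = panel$chrom,
                       positions = panel$positions, line = lines[i])
  })
  list(counts = data.table::rbindlist(tabs), true_freqs = freqs)
}
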