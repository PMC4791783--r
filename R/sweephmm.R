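#' Sweep HMM parameters
#'
#' Three-state (Neutral / Intermediate / Selection) hidden Markov model over
#' ordered SNPs. Each state emits pooled read counts through a state-specific
#' allele-frequency spectrum over derived counts `j = 0..n`; the Selection
#' spectrum concentrates mass on the extreme classes (sweep signature), the
#' Intermediate state is a half-way mixture.
#'
#' @param n Pool size in chromosomes used for the spectrum bins
#'   (default 100; 200 = all chromosomes of a 100-female pool is also
#'   supported).
#' @param k Per-site state-switch probability (default 1e-10).
#' @param theta Scaled mutation rate per site; when `NA` it is estimated
#'   from the data by [estimate_theta()].
#' @param p_e_selection Escape weight of the Selection-state spectrum
#'   toward the Neutral spectrum (default 0.05).
#' @param p_e_intermediate Escape weight of the Intermediate state
#'   (default 0.5).
#' @param anc_prior Probability that a monomorphic site is fixed for the
#'   ancestral allele (splits the monomorphic mass; default 0.5).
#' @param min_depth,max_depth Depth bounds for usable sites (defaults 5,
#'   400).
#' @param min_baseq Minimum base quality (kept for interface completeness;
#'   count tables are assumed pre-filtered; default 20).
#' @return Object of class `hmm_params`.
#' @export
hmm_params <- function(n = 100, k = 1e-10, theta = NA,
                       p_e_selection = 0.05, p_e_intermediate = 0.5,
                       anc_prior = 0.5, min_depth = 5, max_depth = 400,
                       min_baseq = 20) {
  stopifnot(n >= 2, k > 0, k < 0.5, min_depth <= max_depth,
            p_e_selection >= 0, p_e_selection <= 1,
            p_e_intermediate >= 0, p_e_intermediate <= 1,
            anc_prior >= 0, anc_prior <= 1)
  structure(list(n = as.integer(n), k = k, theta = theta,
                 p_e_selection = p_e_selection,
                 p_e_intermediate = p_e_intermediate,
                 anc_prior = anc_prior,
                 min_depth = min_depth, max_depth = max_depth,
                 min_baseq = min_baseq),
            class = "hmm_params")
}

#' Watterson estimate of theta per site
#'
#' `theta = S / (a1 * L)` where `S` is the number of segregating sites
#' observed over `L` covered bp and `a1 = sum_{i<n} 1/i`. Mirrors setting
#' the HMM's theta to the per-sample estimate.
#'
#' @param n_segregating Number of segregating sites.
#' @param n Sample size in chromosomes.
#' @param covered_bp Number of covered bases.
#' @return Per-site theta estimate.
#' @export
estimate_theta <- function(n_segregating, n, covered_bp) {
  stopifnot(covered_bp > 0)
  n_segregating / (tajima_constants(n)$a1 * covered_bp)
}

#' Per-state allele-frequency spectra
#'
#' Neutral: polymorphic classes `j = 1..n-1` get mass `theta / j`, the
#' remaining `1 - theta * a1` sits on the monomorphic classes `{0, n}`
#' split by `anc_prior`. Selection: mixture
#' `(1 - p_e) * (monomorphic point mass) + p_e * Neutral`; Intermediate the
#' same with its own escape weight. All spectra sum to one.
#'
#' @param params An [hmm_params()] with `theta` set.
#' @return Matrix `(n+1) x 3` (`j` in rows, states
#'   `neutral, intermediate, selection` in columns), each column summing
#'   to 1.
#' @export
state_spectra <- function(params) {
  n <- params$n
  theta <- params$theta
  if (is.na(theta) || theta <= 0) stop("theta must be positive")
  a1 <- tajima_constants(n)$a1
  if (theta * a1 >= 1)
    stop("theta too large: polymorphic mass exceeds 1")
  j <- 0:n
  neutral <- numeric(n + 1)
  neutral[2:n] <- theta / (1:(n - 1))
  mono <- 1 - theta * a1
  neutral[1] <- mono * params$anc_prior
  neutral[n + 1] <- mono * (1 - params$anc_prior)
  extreme <- numeric(n + 1)
  extreme[1] <- params$anc_prior
  extreme[n + 1] <- 1 - params$anc_prior
  mix <- function(p_e) (1 - p_e) * extreme + p_e * neutral
  out <- cbind(neutral = neutral,
               intermediate = mix(params$p_e_intermediate),
               selection = mix(params$p_e_selection))
  rownames(out) <- j
  out
}

# log emission matrix: sites x states;
# log P(alt | depth, state) = log sum_j xi_state(j) Binom(alt; depth, j/n)
emission_loglik <- function(alt, depth, params) {
  spectra <- state_spectra(params)
  n <- params$n
  probs <- (0:n) / n
  # B[site, j] = Binom(alt; depth, j/n)
  B <- vapply(probs, function(p) dbinom(alt, depth, p),
              numeric(length(alt)))
  if (length(alt) == 1) B <- matrix(B, nrow = 1)
  log(B %*% spectra)
}

#' Decode the sweep HMM over one chromosome of one line
#'
#' Forward-backward posterior decoding (and Viterbi) of the three-state
#' sweep HMM. The transition matrix has off-diagonal `k` and diagonal
#' `1 - 2k`; being doubly stochastic its stationary distribution is
#' uniform, which is used as the initial distribution. All computations
#' are in log space.
#'
#' @param sites data.table with `pos, alt_count, depth`, ordered by
#'   position.
#' @param params An [hmm_params()]; if `theta` is `NA` it is estimated
#'   from the segregating sites over the span of the input.
#' @param method `"posterior"` (default, per-site argmax of posteriors)
#'   or `"viterbi"`.
#' @param covered_bp Optional number of covered sites backing the theta
#'   estimate (default: the number of input rows; pass the chromosome
#'   length for pileup-complete data).
#' @return data.table `pos, alt_count, depth, p_neutral, p_intermediate,
#'   p_selection, state`; attribute `loglik` carries the total
#'   log-likelihood. Sites outside the depth bounds are dropped.
#' @export
hmm_decode <- function(sites, params = hmm_params(),
                       method = c("posterior", "viterbi"),
                       covered_bp = NULL) {
  method <- match.arg(method)
  dt <- as.data.table(sites)
  if (nrow(dt) && is.unsorted(dt$pos, strictly = FALSE))
    stop("sites must be ordered by position")
  dt <- dt[depth >= params$min_depth & depth <= params$max_depth]
  if (!nrow(dt)) return(data.table())
  if (is.na(params$theta)) {
    # covered sites = rows of the input table (for a pileup-style input
    # every covered position is a row; for a SNP table the SNPs are the
    # covered sites); capped so the polymorphic mass stays below 1
    S <- sum(dt$alt_count > 0 & dt$alt_count < dt$depth)
    a1 <- tajima_constants(params$n)$a1
    if (is.null(covered_bp)) covered_bp <- nrow(dt)
    params$theta <- max(min(estimate_theta(S, params$n, covered_bp),
                            0.999 / a1), 1e-8)
  }
  logE <- emission_loglik(dt$alt_count, dt$depth, params)
  k <- params$k
  logT <- log(matrix(c(1 - 2 * k, k, k,
                       k, 1 - 2 * k, k,
                       k, k, 1 - 2 * k), 3, 3, byrow = TRUE))
  ns <- nrow(dt)
  lse <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }
  # forward
  la <- matrix(-Inf, ns, 3)
  la[1, ] <- log(1 / 3) + logE[1, ]
  for (t in 2:max(ns, 2)) {
    if (t > ns) break
    for (s in 1:3) la[t, s] <- lse(la[t - 1, ] + logT[, s]) + logE[t, s]
  }
  # backward
  lb <- matrix(0, ns, 3)
  if (ns >= 2) {
    for (t in (ns - 1):1) {
      for (s in 1:3) lb[t, s] <- lse(logT[s, ] + logE[t + 1, ] + lb[t + 1, ])
    }
  }
  loglik <- lse(la[ns, ])
  post <- exp(la + lb - loglik)
  post <- post / rowSums(post)
  states <- c("neutral", "intermediate", "selection")
  dec <- if (method == "posterior") {
    states[max.col(post, ties.method = "first")]
  } else {
    viterbi_path(logE, logT)
  }
  out <- dt[, .(pos, alt_count, depth)]
  out[, `:=`(p_neutral = post[, 1], p_intermediate = post[, 2],
             p_selection = post[, 3], state = dec)]
  setattr(out, "loglik", loglik)
  out[]
}

viterbi_path <- function(logE, logT) {
  ns <- nrow(logE)
  states <- c("neutral", "intermediate", "selection")
  v <- matrix(-Inf, ns, 3)
  bp <- matrix(0L, ns, 3)
  v[1, ] <- log(1 / 3) + logE[1, ]
  if (ns >= 2) {
    for (t in 2:ns) {
      for (s in 1:3) {
        cand <- v[t - 1, ] + logT[, s]
        bp[t, s] <- which.max(cand)
        v[t, s] <- cand[bp[t, s]] + logE[t, s]
      }
    }
  }
  path <- integer(ns)
  path[ns] <- which.max(v[ns, ])
  if (ns >= 2) for (t in (ns - 1):1) path[t] <- bp[t + 1, path[t + 1]]
  states[path]
}

#' Merge decoded Selection runs into sweep regions
#'
#' Maximal runs of consecutive SNPs decoded as Selection become regions
#' `[first SNP pos, last SNP pos + 1)` with SNP count and mean Selection
#' posterior.
#'
#' @param decoded Output of [hmm_decode()].
#' @param chrom Chromosome label.
#' @param line Line label.
#' @return data.table `chrom, start, end, line, n_snps, mean_posterior`,
#'   ordered and non-overlapping.
#' @export
call_sweep_regions <- function(decoded, chrom = "chrS", line = "L1") {
  empty <- data.table(chrom = character(), start = integer(),
                      end = integer(), line = character(),
                      n_snps = integer(), mean_posterior = numeric())
  if (!nrow(decoded)) return(empty)
  sel <- decoded$state == "selection"
  if (!any(sel)) return(empty)
  r <- rle(sel)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  rbindlist(lapply(runs, function(i) {
    idx <- starts[i]:ends[i]
    data.table(chrom = chrom,
               start = decoded$pos[idx[1]],
               end = decoded$pos[idx[length(idx)]] + 1L,
               line = line, n_snps = length(idx),
               mean_posterior = mean(decoded$p_selection[idx]))
  }))
}

#' Sweep scan across lines
#'
#' Runs [hmm_decode()] + [call_sweep_regions()] per line and chromosome of
#' a pooled count table.
#'
#' @param counts data.table with `chrom, pos, line, alt_count, depth`.
#' @param params An [hmm_params()].
#' @param merge_gap_bp Regions of one line closer than this are merged
#'   (default 0: no merging).
#' @return data.table of sweep regions over all lines.
#' @export
sweep_scan <- function(counts, params = hmm_params(), merge_gap_bp = 0) {
  dt <- as.data.table(counts)
  out <- dt[order(pos), {
    dec <- hmm_decode(.SD, params)
    r <- call_sweep_regions(dec)
    r[, .(start, end, n_snps, mean_posterior)]
  }, by = .(chrom, line)]
  if (merge_gap_bp > 0 && nrow(out)) {
    out <- out[, merge_close_regions(.SD, merge_gap_bp),
               by = .(chrom, line)]
  }
  out[]
}

merge_close_regions <- function(regions, gap) {
  r <- regions[order(start)]
  ir <- IRanges::reduce(IRanges::IRanges(r$start + 1L, r$end),
                        min.gapwidth = gap)
  data.table(start = IRanges::start(ir) - 1L, end = IRanges::end(ir),
             n_snps = NA_integer_, mean_posterior = NA_real_)
}
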