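# Independent oracles and small fixture builders shared across the suite.

# straight-line reimplementation of the windowed statistics from the
# classical formulas, independent of the package's code path
tajima_oracle <- function(freqs, n) {
  i <- 1:(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  seg <- freqs > 0 & freqs < 1
  S <- sum(seg)
  pi <- sum(2 * freqs[seg] * (1 - freqs[seg])) * n / (n - 1)
  th <- S / a1
  D <- (pi - th) / sqrt(e1 * S + e2 * S * (S - 1))
  list(S = S, H = mean(2 * freqs[seg] * (1 - freqs[seg])),
       pi = pi, theta_w = th, D = D)
}

# exhaustive-path posterior oracle for a 3-state HMM: enumerates all 3^T
# paths in plain probability space
hmm_enum_oracle <- function(E, k) {
  # E: T x 3 matrix of emission probabilities (not logs)
  T_ <- nrow(E)
  trans <- matrix(k, 3, 3); diag(trans) <- 1 - 2 * k
  paths <- as.matrix(expand.grid(rep(list(1:3), T_)))
  w <- apply(paths, 1, function(p) {
    pr <- (1 / 3) * E[1, p[1]]
    for (t in 2:T_) pr <- pr * trans[p[t - 1], p[t]] * E[t, p[t]]
    pr
  })
  post <- matrix(0, T_, 3)
  for (t in 1:T_) for (s in 1:3)
    post[t, s] <- sum(w[paths[, t] == s])
  post / sum(w)
}

# per-basepair brute-force sharing classifier on one small chromosome
brute_sharing <- function(regions, group_map, L) {
  lines <- names(group_map)
  cov <- sapply(lines, function(ln) {
    v <- logical(L)
    r <- regions[regions$line == ln, , drop = FALSE]
    for (i in seq_len(nrow(r)))
      v[(r$start[i] + 1):r$end[i]] <- TRUE
    v
  })
  out <- list()
  for (ln in lines) {
    own <- cov[, ln]
    grp_lines <- lines[group_map == group_map[[ln]]]
    all6 <- rowSums(cov) == length(lines)
    grp <- rowSums(cov[, grp_lines, drop = FALSE]) == length(grp_lines)
    one <- rowSums(cov) == 1
    cls <- rep(NA_character_, L)
    cls[own & all6] <- "all_shared"
    cls[own & !all6 & grp] <- "group_shared"
    cls[own & !all6 & !grp & one] <- "line_specific"
    cls[own & is.na(cls)] <- "other"
    out[[ln]] <- table(factor(cls[own], levels = c(
      "all_shared", "group_shared", "line_specific", "other")))
  }
  out
}

six_line_map <- function() {
  setNames(c(rep("selection", 3), rep("control", 3)),
           c("S1", "S2", "S3", "C1", "C2", "C3"))
}

# a toy diploid-pool record table builder: one row per line per site
make_records <- function(pos, freq_by_line, depth = 50, gq = 60,
                         chrom = "chr1") {
  rows <- list()
  for (ln in names(freq_by_line)) {
    f <- freq_by_line[[ln]]
    alt <- round(f * depth)
    rows[[ln]] <- data.table::data.table(
      chrom = chrom, pos = as.integer(pos), line = ln,
      ref_count = as.integer(depth - alt), alt_count = as.integer(alt),
      depth = as.integer(depth), gq = gq)
  }
  data.table::rbindlist(rows)
}

# random DNA string
random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
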