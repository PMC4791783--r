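#' Forward-simulation configuration
#'
#' Wright-Fisher simulation with recombination over founder haplotypes.
#' The demographic schedule is an ordered table of phases
#' `(generations, N, select)`; the experimental-evolution preset is
#' provided by [experiment_schedule()]. Recombination is parameterised
#' either as a per-Mb rate (`"cM_per_Mb"`) or as the expected number of
#' crossovers per chromosome per meiosis (`"xo_per_chromosome"`, the
#' convention of chromosome-level simulators); crossover counts per gamete
#' are Poisson with breakpoints uniform along the chromosome.
#'
#' @param schedule data.frame with columns `gens`, `N` and optional logical
#'   `select` (whether the selected site's fitness acts in that phase;
#'   default TRUE wherever a selected site is configured).
#' @param recomb_rate Recombination rate (default 2).
#' @param recomb_units `"cM_per_Mb"` (default) or `"xo_per_chromosome"`.
#' @param selected_site Optional list with `pos` (bp), `p0` (initial
#'   frequency), `w` (length-3 fitness of genotypes carrying 0/1/2
#'   beneficial alleles). Default heterozygote fitness is the additive
#'   midpoint.
#' @param final_sample Number of diploids sampled at the end (default:
#'   last phase's N).
#' @param seed Integer seed.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(schedule, recomb_rate = 2,
                       recomb_units = c("cM_per_Mb", "xo_per_chromosome"),
                       selected_site = NULL, final_sample = NULL,
                       seed = 1) {
  recomb_units <- match.arg(recomb_units)
  schedule <- as.data.frame(schedule)
  stopifnot(all(c("gens", "N") %in% names(schedule)),
            nrow(schedule) >= 1, all(schedule$N >= 2),
            all(schedule$gens >= 0), recomb_rate >= 0)
  if (is.null(schedule$select)) schedule$select <- TRUE
  if (!is.null(selected_site)) {
    stopifnot(selected_site$p0 >= 0, selected_site$p0 <= 1,
              all(selected_site$w >= 0))
    if (length(selected_site$w) == 2)
      selected_site$w <- c(selected_site$w[1],
                           mean(selected_site$w),
                           selected_site$w[2])
    stopifnot(length(selected_site$w) == 3)
  }
  structure(list(schedule = schedule, recomb_rate = recomb_rate,
                 recomb_units = recomb_units,
                 selected_site = selected_site,
                 final_sample = final_sample, seed = as.integer(seed)),
            class = "sim_config")
}

#' Experimental-evolution demographic schedule
#'
#' The laboratory design behind the package's simulations: a long
#' mass-breeding phase at large N (equilibration), a 120-founder
#' bottleneck, five generations of mass culture at N = 2000, 48
#' generations of selection at N = 200, ten relaxed generations at N =
#' 200, and a final pool of 100. At full scale the mass-breeding phase is
#' (1000 generations, N = 100,000) — impractical on a desk machine and,
#' for founder panels without linkage disequilibrium, nearly a no-op
#' (per-generation drift ~ 1/2N); `scale` therefore rescales that phase
#' (desk default 100 generations at N = 1000) while later phases keep the
#' experiment's literal values.
#'
#' @param scale `"desk"` (default) or `"full"`.
#' @param include_mass Include the mass-breeding phase (default FALSE: for
#'   LD-free founder panels it only adds runtime; set TRUE to include it).
#' @return data.frame usable as the `schedule` of [sim_config()].
#' @export
experiment_schedule <- function(scale = c("desk", "full"),
                                include_mass = FALSE) {
  scale <- match.arg(scale)
  mass <- if (scale == "full") data.frame(gens = 1000, N = 100000)
          else data.frame(gens = 100, N = 1000)
  core <- data.frame(gens = c(0, 5, 48, 10),
                     N = c(120, 2000, 200, 200),
                     select = c(FALSE, FALSE, TRUE, FALSE))
  # the 120-founder bottleneck is one resampling step (gens = 0 phases
  # still apply their population-size change)
  core$gens[1] <- 1
  if (include_mass) {
    mass$select <- FALSE
    rbind(mass, core)
  } else core
}

#' Run a Wright-Fisher forward simulation
#'
#' Diploid Wright-Fisher resampling with recombination over the haplotypes
#' of a founder panel. Each generation, every offspring draws a parent
#' with probability proportional to fitness (fecundity selection; uniform
#' when neutral) per gamete, and each gamete is a recombinant of the
#' parent's two haplotypes with a Poisson number of uniformly placed
#' crossovers. With a selected site configured, one phase of the schedule
#' can apply genotype fitness `w[gt+1]`; without one the allele-frequency
#' process is a martingale.
#'
#' @param panel A [haplotype_panel()].
#' @param config A [sim_config()].
#' @param het_window_bp Window size of the final heterozygosity profile
#'   (default 100 kb).
#' @return Object of class `sim_result`: `trajectory` (per-generation
#'   selected-allele frequency; length 0 when neutral), `fixed` (logical,
#'   selected allele fixed), `lost` (logical), `final_freqs` (per-site
#'   derived frequencies in the final sample), `positions`, `het_profile`
#'   (data.table `start, end, H`), `panel_final` (haplotype matrix of the
#'   final sample).
#' @export
run_simulation <- function(panel, config, het_window_bp = 1e5) {
  stopifnot(inherits(panel, "haplotype_panel"),
            inherits(config, "sim_config"))
  if (!length(panel$positions)) stop("panel is empty")
  set.seed(derive_seed(config$seed, 8L))
  pos <- panel$positions
  sel <- config$selected_site
  selcol <- NA_integer_
  if (!is.null(sel)) {
    ins <- findInterval(sel$pos, pos)
    pos <- append(pos, as.integer(sel$pos), after = ins)
    selcol <- ins + 1L
  }
  len_mb <- panel$length_bp / 1e6
  mean_xo <- if (config$recomb_units == "cM_per_Mb")
    config$recomb_rate * len_mb / 100 else config$recomb_rate
  # initial population of the first phase
  N <- config$schedule$N[1]
  idx <- sample.int(panel$n_haplotypes, 2 * N, replace = TRUE)
  H <- panel$alleles[idx, , drop = FALSE]
  if (!is.null(sel)) {
    carriers <- round(sel$p0 * 2 * N)
    if (sel$p0 > 0 && carriers == 0)
      stop("p0 too small: no carrier haplotype assignable at 2N = ", 2 * N)
    col <- integer(2 * N)
    if (carriers > 0) col[sample.int(2 * N, carriers)] <- 1L
    left <- seq_len(selcol - 1L)
    right <- setdiff(seq_len(ncol(H)), left)
    H <- cbind(H[, left, drop = FALSE], sel_site = col,
               H[, right, drop = FALSE])
  }
  traj <- numeric(0)
  for (ph in seq_len(nrow(config$schedule))) {
    gens <- config$schedule$gens[ph]
    N_next <- config$schedule$N[ph]
    apply_sel <- !is.null(sel) && isTRUE(config$schedule$select[ph])
    for (g in seq_len(gens)) {
      H <- wf_generation(H, N_next, mean_xo, panel$length_bp, pos,
                         if (apply_sel) sel$w else NULL, selcol)
      if (!is.null(sel)) traj <- c(traj, mean(H[, selcol]))
    }
    if (gens == 0 && N_next != nrow(H) / 2) {
      # pure bottleneck: resample individuals without reproduction
      pick <- sample.int(nrow(H) / 2, N_next, replace = FALSE)
      H <- H[as.vector(rbind(2 * pick - 1, 2 * pick)), , drop = FALSE]
    }
  }
  ns <- config$final_sample
  if (!is.null(ns) && ns < nrow(H) / 2) {
    pick <- sample.int(nrow(H) / 2, ns)
    H <- H[as.vector(rbind(2 * pick - 1, 2 * pick)), , drop = FALSE]
  }
  freqs <- colMeans(H)
  het <- 2 * freqs * (1 - freqs)
  wins <- tile_windows(panel$length_bp, het_window_bp)
  wi <- findInterval(pos, wins$start)
  prof <- data.table(start = wins$start, end = wins$end,
                     H = as.numeric(tapply(het, factor(wi,
                       levels = seq_len(nrow(wins))), mean)))
  structure(list(
    trajectory = traj,
    fixed = if (is.null(sel)) NA else mean(H[, selcol]) == 1,
    lost = if (is.null(sel)) NA else mean(H[, selcol]) == 0,
    final_freqs = freqs, positions = pos, selcol = selcol,
    het_profile = prof, panel_final = H), class = "sim_result")
}

# one Wright-Fisher generation: parents sampled by fitness, gametes
# recombined; the no-crossover fast path is a single matrix indexing
wf_generation <- function(H, N_next, mean_xo, length_bp, pos, w, selcol) {
  N <- nrow(H) / 2
  if (!is.null(w)) {
    gt <- H[seq(1, 2 * N, 2), selcol] + H[seq(2, 2 * N, 2), selcol]
    fit <- w[gt + 1]
    if (all(fit == 0)) stop("population fitness collapsed to zero")
    parents <- sample.int(N, 2 * N_next, replace = TRUE, prob = fit)
  } else {
    parents <- sample.int(N, 2 * N_next, replace = TRUE)
  }
  which_hap <- sample.int(2, 2 * N_next, replace = TRUE)
  nco <- rpois(2 * N_next, mean_xo)
  src <- 2L * parents - 2L + which_hap
  Hn <- H[src, , drop = FALSE]
  for (i in which(nco > 0)) {
    h1 <- H[2L * parents[i] - 2L + which_hap[i], ]
    h2 <- H[2L * parents[i] - 2L + (3L - which_hap[i]), ]
    bp <- sort(runif(nco[i], 0, length_bp))
    seg <- findInterval(pos, bp) %% 2L == 1L
    h1[seg] <- h2[seg]
    Hn[i, ] <- h1
  }
  Hn
}

#' Expected neutral heterozygosity decay
#'
#' Closed-form drift expectation `E[H_t] = H_0 (1 - 1/(2N))^t` for a
#' Wright-Fisher population of `N` diploids after `t` generations; the
#' analytic oracle for neutral-simulation validation.
#'
#' @param N Diploid population size (>= 1).
#' @param t Generations (>= 0).
#' @return The decay factor `(1 - 1/(2N))^t`.
#' @export
expected_neutral_het <- function(N, t) {
  stopifnot(N >= 1, t >= 0)
  (1 - 1 / (2 * N))^t
}

#' @export
print.sim_result <- function(x, ...) {
  cat("sim_result:", length(x$positions), "sites;")
  if (length(x$trajectory))
    cat(" selected allele", if (isTRUE(x$fixed)) "FIXED"
        else if (isTRUE(x$lost)) "LOST" else
          sprintf("at %.3f", tail(x$trajectory, 1)), ";")
  cat(" mean final het", sprintf("%.4f", mean(x$het_profile$H, na.rm = TRUE)),
      "\n")
  invisible(x)
}

#' Contiguous depleted-heterozygosity span around a position
#'
#' Length of the maximal run of windows, containing `center_pos`, whose
#' heterozygosity lies strictly below `frac` times the matched neutral
#' expectation per window.
#'
#' @param het_profile data.table `start, end, H` (selection run).
#' @param neutral_H Numeric vector of per-window neutral heterozygosity
#'   (same windows; e.g. the mean over neutral replicate runs).
#' @param center_pos Position (bp) the span must contain.
#' @param frac Depletion threshold as a fraction of neutral (default 0.5).
#' @return Span in bp (0 when the center window is not depleted).
#' @export
depleted_span <- function(het_profile, neutral_H, center_pos, frac = 0.5) {
  stopifnot(nrow(het_profile) == length(neutral_H))
  below <- !is.na(het_profile$H) & !is.na(neutral_H) &
    het_profile$H < frac * neutral_H
  cw <- which(het_profile$start <= center_pos &
                het_profile$end > center_pos)[1]
  if (is.na(cw) || !below[cw]) return(0)
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  i <- which(starts <= cw & ends >= cw & r$values)
  sum(het_profile$end[starts[i]:ends[i]] -
        het_profile$start[starts[i]:ends[i]])
}

#' Selection-sweep span experiment
#'
#' Runs the package's single-site selection scenario: a selected allele at
#' initial frequency `p0` with genotype fitness `w` on a synthetic
#' chromosome, `gens` generations at `N` diploids, conditioned on fixation
#' of the selected allele, against matched neutral replicates. Returns the
#' widths of the contiguous region around the selected site whose final
#' windowed heterozygosity falls below half the neutral level.
#'
#' @param seed Integer seed.
#' @param n_fix_reps Number of fixation-conditioned replicates (>= 1).
#' @param n_neutral Neutral replicates averaged into the reference profile.
#' @param n_sites Founder segregating sites (default 10,000).
#' @param chrom_length Chromosome length in bp (default 10 Mb).
#' @param N Diploid population size (default 200).
#' @param gens Generations of selection (default 48).
#' @param w Genotype fitness for 0/1/2 copies (default `c(0.2, 2.1, 4)`:
#'   baseline 0.2, beneficial homozygote 4, additive heterozygote).
#' @param p0 Initial selected-allele frequency (default 1/400).
#' @param xo_per_mb Crossover density per Mb per meiosis (default `2/23`:
#'   2 crossovers per chromosome per meiosis, the convention of
#'   chromosome-level forward simulators, on a ~23 Mb chromosome arm).
#' @param window_bp Heterozygosity window (default 100 kb).
#' @param max_attempts Cap on selection runs while collecting fixations.
#' @return List: `spans_mb` (per fixation replicate), `mean_span_mb`,
#'   `n_fixed`, `n_attempts`, `neutral_H` and the window table.
#' @export
sweep_span_experiment <- function(seed, n_fix_reps = 10, n_neutral = 3,
                                  n_sites = 10000, chrom_length = 1e7,
                                  N = 200, gens = 48,
                                  w = c(0.2, 2.1, 4), p0 = 1 / 400,
                                  xo_per_mb = 2 / 23,
                                  window_bp = 1e5,
                                  max_attempts = 10 * n_fix_reps) {
  xo <- xo_per_mb * chrom_length / 1e6
  panel <- gen_founder_panel(205, n_sites, chrom_length,
                             seed = derive_seed(seed, 20L))
  sel_pos <- round(chrom_length / 2)
  sched <- data.frame(gens = gens, N = N, select = TRUE)
  neutral <- lapply(seq_len(n_neutral), function(i) {
    cfg <- sim_config(sched, recomb_rate = xo,
                      recomb_units = "xo_per_chromosome",
                      seed = derive_seed(seed, 30L + i))
    run_simulation(panel, cfg, het_window_bp = window_bp)$het_profile
  })
  neutral_H <- rowMeans(do.call(cbind, lapply(neutral, `[[`, "H")),
                        na.rm = TRUE)
  spans <- numeric(0)
  attempts <- 0L
  while (length(spans) < n_fix_reps && attempts < max_attempts) {
    attempts <- attempts + 1L
    cfg <- sim_config(sched, recomb_rate = xo,
                      recomb_units = "xo_per_chromosome",
                      selected_site = list(pos = sel_pos, p0 = p0, w = w),
                      seed = derive_seed(seed, 100L + attempts))
    r <- run_simulation(panel, cfg, het_window_bp = window_bp)
    if (!isTRUE(r$fixed)) next
    spans <- c(spans, depleted_span(r$het_profile, neutral_H, sel_pos))
  }
  list(spans_mb = spans / 1e6, mean_span_mb = mean(spans) / 1e6,
       n_fixed = length(spans), n_attempts = attempts,
       neutral_H = neutral_H,
       windows = neutral[[1]][, c("start", "end")])
}

#' Load a simulation configuration from YAML
#'
#' Reads a YAML file with keys `schedule` (list of `{gens, N, select}`),
#' `recomb_rate`, `recomb_units`, `selected_site` (`{pos, p0, w}`),
#' `final_sample` and `seed`, and builds a [sim_config()].
#'
#' @param path YAML file path.
#' @return A [sim_config()].
#' @export
sim_config_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  sched <- do.call(rbind, lapply(y$schedule, function(ph) {
    # YAML 1.1 coerces a bare N key to boolean FALSE; map it back
    names(ph)[names(ph) %in% c("FALSE", "false")] <- "N"
    as.data.frame(ph)
  }))
  sim_config(schedule = sched,
             recomb_rate = y$recomb_rate %||% 2,
             recomb_units = y$recomb_units %||% "cM_per_Mb",
             selected_site = if (!is.null(y$selected_site))
               list(pos = y$selected_site$pos, p0 = y$selected_site$p0,
                    w = unlist(y$selected_site$w)),
             final_sample = y$final_sample,
             seed = y$seed %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
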