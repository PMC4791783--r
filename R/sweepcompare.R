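#' Classify sweep-region sharing across replicate lines
#'
#' Works at base-pair resolution by interval algebra: a base is
#' `all_shared` when covered by the sweep regions of every line,
#' `group_shared` (for a line) when covered by every line of that line's
#' group, `line_specific` when covered by exactly one line overall, and
#' `other` otherwise. Each line's input regions are partitioned into
#' disjoint classified segments, so per line the class lengths sum to the
#' input region lengths.
#'
#' @param regions data.table `chrom, start, end, line` (0-based half-open,
#'   non-overlapping within a line; overlapping input is an error, merge
#'   first).
#' @param group_map Named character vector line -> group (two groups).
#' @return data.table `chrom, start, end, line, class`.
#' @export
classify_sharing <- function(regions, group_map) {
  dt <- as.data.table(regions)
  lines <- names(group_map)
  groups <- unique(group_map)
  out <- dt[, classify_sharing_chrom(.SD, group_map), by = chrom]
  out[]
}

classify_sharing_chrom <- function(dt, group_map) {
  lines <- names(group_map)
  ir_of <- function(ln) {
    r <- dt[line == ln]
    ir <- IRanges::IRanges(r$start + 1L, r$end)
    if (length(ir) > 1 && !IRanges::isDisjoint(ir))
      stop("overlapping regions within line ", ln, "; pre-merge them")
    ir
  }
  irs <- lapply(setNames(lines, lines), ir_of)
  inter_all <- function(sets) {
    if (!length(sets)) return(IRanges::IRanges())
    Reduce(IRanges::intersect, sets)
  }
  all_mask <- inter_all(irs)
  grp_mask <- lapply(setNames(unique(group_map), unique(group_map)),
                     function(g) inter_all(irs[names(group_map)[
                       group_map == g]]))
  width <- max(dt$end)
  cov <- Reduce(`+`, lapply(irs, IRanges::coverage, width = width))
  one_mask <- methods::as(IRanges::slice(cov, lower = 1, upper = 1),
                          "IRanges")
  res <- lapply(lines, function(ln) {
    ir <- irs[[ln]]
    if (!length(ir)) return(NULL)
    seg_all <- IRanges::intersect(ir, all_mask)
    rest <- IRanges::setdiff(ir, seg_all)
    seg_grp <- IRanges::intersect(rest, grp_mask[[group_map[[ln]]]])
    rest <- IRanges::setdiff(rest, seg_grp)
    seg_one <- IRanges::intersect(rest, one_mask)
    seg_oth <- IRanges::setdiff(rest, seg_one)
    mk <- function(ir, cls) if (!length(ir)) NULL else
      data.table(start = IRanges::start(ir) - 1L,
                 end = IRanges::end(ir), line = ln, class = cls)
    rbindlist(list(mk(seg_all, "all_shared"),
                   mk(seg_grp, "group_shared"),
                   mk(seg_one, "line_specific"),
                   mk(seg_oth, "other")))
  })
  out <- rbindlist(res[!vapply(res, is.null, logical(1))])
  if (!nrow(out))
    out <- data.table(start = integer(), end = integer(),
                      line = character(), class = character())
  out[order(line, start)]
}

#' Shared sweep-length statistics per group
#'
#' Totals of base pairs covered by the sweep regions of every line of each
#' group (the group-shared masks), the ratio between the two groups, the
#' per-group mean input region length, and an autosome/X split (chromosome
#' names containing `"X"` are treated as X-linked).
#'
#' @param regions data.table `chrom, start, end, line`.
#' @param group_map Named character vector line -> group.
#' @param ratio_groups Length-2 character: numerator and denominator group
#'   of the reported ratio (default the two groups sorted, first over
#'   second).
#' @return List with `shared_bp` (per group x chromosome class),
#'   `total_shared` (per group), `ratio` (`Inf` flagged when the
#'   denominator group shares nothing), `mean_region_length` per group.
#' @export
shared_length_stats <- function(regions, group_map, ratio_groups = NULL) {
  dt <- as.data.table(regions)
  groups <- sort(unique(group_map))
  if (is.null(ratio_groups)) ratio_groups <- groups
  shared <- dt[, {
    masks <- lapply(setNames(groups, groups), function(g) {
      sets <- lapply(names(group_map)[group_map == g], function(ln) {
        r <- .SD[line == ln]
        IRanges::IRanges(r$start + 1L, r$end)
      })
      Reduce(IRanges::intersect, sets)
    })
    rbindlist(lapply(groups, function(g)
      data.table(group = g, shared_bp = sum(IRanges::width(masks[[g]])))))
  }, by = chrom]
  shared[, chrom_class := ifelse(grepl("X", chrom), "X", "autosome")]
  total <- shared[, .(shared_bp = sum(shared_bp)), by = group]
  num <- total[group == ratio_groups[1], shared_bp]
  den <- total[group == ratio_groups[2], shared_bp]
  ratio <- if (!length(den) || den == 0) Inf else num / den
  mean_len <- dt[, .(mean_length = mean(end - start)),
                 by = .(group = group_map[line])]
  list(shared_bp = shared[],
       total_shared = total[],
       ratio = ratio,
       ratio_infinite = !is.finite(ratio),
       mean_region_length = mean_len[])
}

#' Hard-sweep candidate rule
#'
#' Line-specific sweep regions qualify as hard-sweep candidates when their
#' mean in-region heterozygosity does not exceed `max_mean_het` and they
#' lie at least `min_distance_bp` from any group-shared or all-shared
#' region (isolation from parallel sweep signatures).
#'
#' @param max_mean_het Maximum mean heterozygosity inside the region
#'   (default 0.01).
#' @param min_distance_bp Minimum distance to the nearest shared region
#'   (default 100 kb, one heterozygosity window).
#' @return Object of class `hard_sweep_rule`.
#' @export
hard_sweep_rule <- function(max_mean_het = 0.01, min_distance_bp = 1e5) {
  stopifnot(max_mean_het >= 0, max_mean_het <= 0.5, min_distance_bp >= 0)
  structure(list(max_mean_het = max_mean_het,
                 min_distance_bp = min_distance_bp),
            class = "hard_sweep_rule")
}

#' Call hard-sweep candidates among line-specific regions
#'
#' @param classified Output of [classify_sharing()].
#' @param het_windows data.table `chrom, line, start, end, H` of windowed
#'   heterozygosity (column `H`).
#' @param rule A [hard_sweep_rule()].
#' @return data.table of candidate regions with `mean_het` and
#'   `dist_to_shared`; regions without overlapping heterozygosity windows
#'   are skipped with a warning.
#' @export
hard_sweep_candidates <- function(classified, het_windows,
                                  rule = hard_sweep_rule()) {
  cl <- as.data.table(classified)
  hw <- as.data.table(het_windows)
  spec <- cl[class == "line_specific"]
  shared <- cl[class %in% c("group_shared", "all_shared")]
  empty <- data.table(chrom = character(), start = integer(),
                      end = integer(), line = character(),
                      mean_het = numeric(), dist_to_shared = numeric())
  if (!nrow(spec)) return(empty)
  rows <- lapply(seq_len(nrow(spec)), function(i) {
    r <- spec[i]
    win <- hw[chrom == r$chrom & line == r$line &
                start < r$end & end > r$start]
    if (!nrow(win)) {
      warning("no heterozygosity data overlapping ", r$chrom, ":",
              r$start, "-", r$end, " (", r$line, "); region skipped")
      return(NULL)
    }
    # prefer windows fully inside the region; boundary-straddling windows
    # mix in flanking diversity and only serve as a fallback for regions
    # shorter than one window
    inside <- win[start >= r$start & end <= r$end]
    if (nrow(inside)) win <- inside
    mh <- mean(win$H, na.rm = TRUE)
    sh <- shared[chrom == r$chrom]
    dist <- if (!nrow(sh)) Inf else {
      q <- IRanges::IRanges(r$start + 1L, r$end)
      s <- IRanges::IRanges(sh$start + 1L, sh$end)
      min(IRanges::distance(rep(q, length(s)), s))
    }
    data.table(chrom = r$chrom, start = r$start, end = r$end,
               line = r$line, mean_het = mh, dist_to_shared = dist)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- rbindlist(rows)
  out[is.na(mean_het) == FALSE & mean_het <= rule$max_mean_het &
        dist_to_shared >= rule$min_distance_bp][]
}

#' Positional clustering permutation test
#'
#' Tests whether focal positions are more tightly clustered than expected
#' for a random draw from the background positions. The statistic is the
#' mean nearest-neighbour distance among the focal positions; the null
#' distribution resamples `|focal|` positions from the background without
#' replacement `R` times, and the p-value uses the add-one estimator
#' `p = (1 + #{null <= observed}) / (R + 1)`.
#'
#' @param focal Integer positions of interest (>= 2, subset of
#'   `background`).
#' @param background Integer positions of the eligible universe.
#' @param R Number of permutations (default 1e5).
#' @param seed Integer seed.
#' @return List with `p.value`, `observed`, and the vector `null` of
#'   permuted statistics.
#' @export
cluster_permutation_test <- function(focal, background, R = 1e5, seed = 1) {
  if (length(focal) < 2) stop("need at least two focal positions")
  if (!all(focal %in% background))
    stop("focal positions must be a subset of the background")
  mnnd <- function(x) {
    x <- sort(x)
    d <- diff(x)
    mean(pmin(c(d, Inf), c(Inf, d)))
  }
  obs <- mnnd(focal)
  set.seed(derive_seed(seed, 7L))
  null <- vapply(seq_len(R), function(i)
    mnnd(sample(background, length(focal))), numeric(1))
  list(p.value = (1 + sum(null <= obs)) / (R + 1),
       observed = obs, null = null)
}
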