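#' Variant filter configuration
#'
#' Site-level quality filters applied before any downstream analysis:
#' genotype quality, depth bounds, proximity to indels, biallelic
#' restriction, and the fixation threshold used to call a pooled genotype
#' fixed (reference fraction strictly above `fixation_threshold` or
#' strictly below `1 - fixation_threshold`).
#'
#' @param min_gq Minimum genotype quality (exclusive; default 30).
#' @param min_depth,max_depth Depth bounds (inclusive; defaults 10, 250).
#' @param indel_buffer_bp Remove SNPs within this distance of any base of
#'   an indel's reference span, inclusive (default 10).
#' @param biallelic_only Drop sites with more than two alleles (default).
#' @param fixation_threshold Fixation rule threshold in `(0.5, 1]`
#'   (default 0.99; comparisons are strict).
#' @return Object of class `filter_config`.
#' @export
filter_config <- function(min_gq = 30, min_depth = 10, max_depth = 250,
                          indel_buffer_bp = 10, biallelic_only = TRUE,
                          fixation_threshold = 0.99) {
  stopifnot(min_depth <= max_depth, fixation_threshold > 0.5,
            fixation_threshold <= 1)
  structure(list(min_gq = min_gq, min_depth = min_depth,
                 max_depth = max_depth, indel_buffer_bp = indel_buffer_bp,
                 biallelic_only = biallelic_only,
                 fixation_threshold = fixation_threshold),
            class = "filter_config")
}

#' Filter raw pooled variant records
#'
#' Keeps only sites at which every line passes the quality and depth
#' thresholds, removes SNPs near indels and multi-allelic sites, and
#' annotates the surviving records with per-line frequency and fixation
#' status. Filtering is idempotent.
#'
#' @param records data.table with columns `chrom, pos, line, ref_count,
#'   alt_count, depth, gq`; optional `n_alleles`.
#' @param config A [filter_config()].
#' @param indels Optional data.table of indels with `chrom, start, end`
#'   (0-based half-open reference span).
#' @return Filtered data.table with added `freq` (alt fraction) and
#'   `status` columns.
#' @export
filter_variants <- function(records, config = filter_config(),
                            indels = NULL) {
  dt <- as.data.table(records)
  bad <- dt[alt_count + ref_count != depth]
  if (nrow(bad))
    stop("malformed record: counts do not sum to depth at ",
         bad$chrom[1], ":", bad$pos[1])
  if (config$biallelic_only && "n_alleles" %in% names(dt))
    dt <- dt[n_alleles <= 2]
  # a site survives only if every line passes gq/depth at that site
  dt[, `:=`(ok = gq > config$min_gq & depth >= config$min_depth &
              depth <= config$max_depth)]
  keep <- dt[, .(all_ok = all(ok)), by = .(chrom, pos)][all_ok == TRUE]
  dt <- dt[keep[, .(chrom, pos)], on = c("chrom", "pos")]
  dt[, ok := NULL]
  if (!is.null(indels) && nrow(indels) && nrow(dt)) {
    idt <- as.data.table(indels)
    idt <- idt[, .(chrom,
                   wstart = start - config$indel_buffer_bp,
                   wend = end + config$indel_buffer_bp)]
    hit <- dt[idt, on = .(chrom, pos >= wstart, pos < wend),
              which = TRUE, nomatch = NULL]
    if (length(hit)) dt <- dt[-unique(hit)]
  }
  if (nrow(dt)) {
    dt[, freq := ifelse(depth > 0, alt_count / depth, NA_real_)]
    dt[, status := fixation_status(freq, config)]
  } else {
    dt[, `:=`(freq = numeric(0), status = character(0))]
  }
  dt[]
}

#' Fixation status of a pooled genotype
#'
#' A site is `fixed_alt` when the alternate fraction strictly exceeds the
#' threshold (reference fraction < 1 - threshold), `fixed_ref` when the
#' reference fraction strictly exceeds it, otherwise `polymorphic`;
#' missing frequencies give `missing`.
#'
#' @param freq Alternate-allele fraction(s) in `[0, 1]` (NA allowed).
#' @param config A [filter_config()]; only `fixation_threshold` is used.
#' @return Character vector over
#'   `{"fixed_ref", "fixed_alt", "polymorphic", "missing"}`.
#' @export
fixation_status <- function(freq, config = filter_config()) {
  th <- config$fixation_threshold
  out <- rep("polymorphic", length(freq))
  out[!is.na(freq) & freq > th] <- "fixed_alt"
  # reference fraction strictly above the threshold (written this way so
  # that e.g. an alternate fraction of exactly 0.01 stays polymorphic
  # without floating-point surprises from 1 - 0.99)
  out[!is.na(freq) & (1 - freq) > th] <- "fixed_ref"
  out[is.na(freq)] <- "missing"
  out
}

#' Scan per-site fixation patterns across groups
#'
#' For each site, determines whether each group has the same allele fixed
#' in every one of its lines, whether the two groups are fixed for
#' alternative alleles (`experiment_specific`), and whether five of the six
#' lines share one fixed allele while a single line is fixed for the other
#' (`single_line_discordant`, reporting that line).
#'
#' @param table Filtered records from [filter_variants()] (needs `chrom,
#'   pos, line, status`).
#' @param group_map Named character vector mapping line -> group; exactly
#'   two groups.
#' @return data.table keyed by site with logical flags
#'   `group_fixed_<group>` per group, `experiment_specific`, and
#'   `single_line_discordant` (line id or NA).
#' @export
scan_site_patterns <- function(table, group_map) {
  groups <- sort(unique(group_map))
  if (length(groups) != 2) stop("exactly two groups required")
  dt <- as.data.table(table)
  dt[, grp := group_map[line]]
  wide <- dt[, .(
    n_lines = .N,
    n_missing = sum(status == "missing"),
    g1_ref = all(status[grp == groups[1]] == "fixed_ref"),
    g1_alt = all(status[grp == groups[1]] == "fixed_alt"),
    g2_ref = all(status[grp == groups[2]] == "fixed_ref"),
    g2_alt = all(status[grp == groups[2]] == "fixed_alt"),
    n_ref = sum(status == "fixed_ref"),
    n_alt = sum(status == "fixed_alt"),
    alt_line = if (sum(status == "fixed_alt") == 1L)
      line[status == "fixed_alt"] else NA_character_,
    ref_line = if (sum(status == "fixed_ref") == 1L)
      line[status == "fixed_ref"] else NA_character_
  ), by = .(chrom, pos)]
  n_total <- length(group_map)
  out <- wide[, .(
    chrom, pos,
    gf1 = g1_ref | g1_alt,
    gf2 = g2_ref | g2_alt,
    experiment_specific = (g1_ref & g2_alt) | (g1_alt & g2_ref),
    single_line_discordant = ifelse(
      n_missing == 0 & n_lines == n_total &
        ((n_ref == n_total - 1L & n_alt == 1L) |
           (n_alt == n_total - 1L & n_ref == 1L)),
      ifelse(n_alt == 1L, alt_line, ref_line), NA_character_),
    incomplete = n_missing > 0 | n_lines < n_total
  )]
  # sites with a missing call carry null (NA) pattern flags
  out[incomplete == TRUE,
      `:=`(gf1 = NA, gf2 = NA, experiment_specific = NA,
           single_line_discordant = NA_character_)]
  setnames(out, c("gf1", "gf2"),
           paste0("group_fixed_", groups))
  out[, incomplete := NULL]
  out[]
}

#' SNP category density table
#'
#' Per functional category: SNP count, percentage of all SNPs, sequencing
#' coverage (callable bp) and SNP density per Kb
#' (`1000 * count / coverage`), with a `Total` row. Layout follows the
#' standard genome-scan summary table.
#'
#' @param counts Named integer vector of SNP counts per category.
#' @param coverage_bp Named numeric vector of covered bp per category;
#'   categories with nonzero count require nonzero coverage. Synonymous and
#'   non-synonymous CDS counts may share one CDS coverage entry named
#'   `"cds"`.
#' @param total_coverage_bp Total callable bp for the `Total` row
#'   (default: sum of unique coverage entries).
#' @return data.table `category, count, percent, coverage, density_per_kb`
#'   (percent and density rounded to 2 decimals).
#' @export
category_density_table <- function(counts, coverage_bp,
                                   total_coverage_bp = NULL) {
  cats <- names(counts)
  total <- sum(counts)
  cov <- vapply(cats, function(cc) {
    key <- if (cc %in% names(coverage_bp)) cc else
      if (startsWith(cc, "cds")) "cds" else cc
    if (!key %in% names(coverage_bp)) NA_real_ else coverage_bp[[key]]
  }, numeric(1))
  if (any(!is.na(cov) & cov == 0 & counts > 0))
    stop("zero coverage with nonzero count")
  if (is.null(total_coverage_bp))
    total_coverage_bp <- sum(coverage_bp)
  dens <- ifelse(is.na(cov) | cov == 0, NA_real_,
                 round(1000 * counts / cov, 2))
  dt <- data.table(category = cats, count = as.integer(counts),
                   percent = round(100 * counts / max(total, 1), 2),
                   coverage = cov, density_per_kb = dens)
  rbind(dt, data.table(category = "Total", count = as.integer(total),
                       percent = 100.00, coverage = total_coverage_bp,
                       density_per_kb =
                         round(1000 * total / total_coverage_bp, 2)))
}

#' Fisher test for coding enrichment between two site classes
#'
#' Two-sided Fisher exact test comparing the fraction `k1/n1` against
#' `k2/n2` (e.g. coding fractions of fixed sites in two groups), on the
#' table `[[k1, n1-k1], [k2, n2-k2]]`.
#'
#' @param k1,n1 Successes and total in group 1 (`0 <= k1 <= n1`).
#' @param k2,n2 Successes and total in group 2.
#' @return List with `odds.ratio` and `p.value`.
#' @export
enrichment_fisher <- function(k1, n1, k2, n2) {
  if (n1 == 0 || n2 == 0) stop("group totals must be positive")
  stopifnot(k1 >= 0, k1 <= n1, k2 >= 0, k2 <= n2)
  fisher_exact_2x2(k1, n1 - k1, k2, n2 - k2)
}
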