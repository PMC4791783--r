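#' Pipeline configuration
#'
#' Bundles the per-stage settings of the end-to-end analysis: line-to-group
#' assignment, variant filters, window specifications, HMM parameters, the
#' hard-sweep rule and the permutation budget.
#'
#' @param group_map Named character vector line -> group; exactly two
#'   groups with at least one line each.
#' @param filter A [filter_config()].
#' @param div_window [window_spec()] for pi/theta/D (default 10 kb tiles).
#' @param het_window [window_spec()] for heterozygosity (default 100 kb
#'   windows, 10 kb step).
#' @param hmm An [hmm_params()].
#' @param hard_rule A [hard_sweep_rule()].
#' @param perm_R Permutations for the clustering test (default 1000).
#' @param n_chromosomes Pool size in chromosomes for diversity statistics
#'   (default 200).
#' @param out_dir Output directory (created if missing); `NULL` disables
#'   file output.
#' @param seed Integer seed governing every stochastic stage.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(group_map,
                            filter = filter_config(),
                            div_window = window_spec(10000, 10000),
                            het_window = window_spec(100000, 10000),
                            hmm = hmm_params(),
                            hard_rule = hard_sweep_rule(),
                            perm_R = 1000,
                            n_chromosomes = 200,
                            out_dir = NULL,
                            seed = 1) {
  if (is.null(names(group_map)) || any(names(group_map) == ""))
    stop("missing config key: group_map must be a named vector")
  groups <- unique(group_map)
  if (length(groups) != 2)
    stop("group_map must define exactly two groups, got ",
         length(groups))
  structure(list(group_map = group_map, filter = filter,
                 div_window = div_window, het_window = het_window,
                 hmm = hmm, hard_rule = hard_rule, perm_R = perm_R,
                 n_chromosomes = n_chromosomes,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Bundled synthetic fixture for the pipeline
#'
#' Generates the default end-to-end input: a founder panel on a small
#' chromosome, six replicate pools (three selection, three control) with
#' one soft sweep spiked into all selection lines and one hard sweep into
#' a single selection line, plus a gene set with mixed MK targets.
#'
#' @param config A [pipeline_config()].
#' @param n_sites Founder sites (default 3000).
#' @param chrom_length Chromosome length (default 3 Mb).
#' @return List with `panel`, `counts`, `true_freqs`, `gene_set`,
#'   `soft_region`, `hard_region`, `hard_line`.
#' @export
pipeline_fixture <- function(config, n_sites = 3000, chrom_length = 3e6) {
  gm <- config$group_map
  sel_lines <- names(gm)[gm == unique(gm)[1]]
  panel <- gen_founder_panel(205, n_sites, chrom_length,
                            seed = derive_seed(config$seed, 10L))
  soft_region <- c(round(chrom_length * 0.2), round(chrom_length * 0.3))
  hard_region <- c(round(chrom_length * 0.6), round(chrom_length * 0.7))
  hard_line <- sel_lines[1]
  ex <- gen_pool_experiment(
    panel, lines = names(gm),
    config = pool_sampling_config(seed = derive_seed(config$seed, 11L)),
    sweeps = list(
      list(region = soft_region, mode = "soft", replicate_ids = sel_lines),
      list(region = hard_region, mode = "hard", replicate_ids = hard_line)),
    seed = derive_seed(config$seed, 12L))
  gs <- gen_mk_gene_set(
    n_genes = 6, codons_per_gene = 120,
    targets = data.frame(DS = c(2, 3, 1, 0, 2, 1),
                         DN = c(2, 2, 2, 2, 0, 1),
                         PS = c(22, 21, 14, 20, 0, 5),
                         PN = c(0, 0, 0, 0, 8, 5)),
    seed = derive_seed(config$seed, 13L))
  list(panel = panel, counts = ex$counts, true_freqs = ex$true_freqs,
       gene_set = gs, soft_region = soft_region,
       hard_region = hard_region, hard_line = hard_line)
}

#' Run the end-to-end analysis
#'
#' Orchestrates filtering, fixation-pattern scanning, windowed diversity,
#' HMM sweep detection per line, cross-replicate sharing classification,
#' hard-sweep candidate calling, the positional clustering test on
#' experiment-specific sites, and the MK/Ka-Ks table, writing TSV/BED
#' outputs and a machine-readable JSON summary when `out_dir` is set. The
#' whole run is a pure function of the inputs and `config$seed`.
#'
#' @param config A [pipeline_config()].
#' @param inputs Optional list with `counts` (pooled site records),
#'   `gene_set`, and optionally `chrom_length`; when `NULL`, the bundled
#'   synthetic fixture from [pipeline_fixture()] is generated and
#'   analysed.
#' @return List of stage results: `patterns, density, diversity,
#'   het_windows, regions, sharing, shared_stats, hard_candidates,
#'   clustering, mk, summary` (the JSON-serialisable summary).
#' @export
run_pipeline <- function(config, inputs = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  fixture <- NULL
  if (is.null(inputs)) {
    fixture <- pipeline_fixture(config)
    inputs <- list(counts = fixture$counts, gene_set = fixture$gene_set,
                   chrom_length = fixture$panel$length_bp)
  }
  counts <- as.data.table(inputs$counts)
  missing_lines <- setdiff(unique(counts$line), names(config$group_map))
  if (length(missing_lines))
    stop("inconsistent line names across inputs: ",
         paste(missing_lines, collapse = ", "))
  chrom_length <- inputs$chrom_length
  if (is.null(chrom_length)) chrom_length <- max(counts$pos) + 1

  filtered <- filter_variants(counts, config$filter)
  patterns <- scan_site_patterns(filtered, config$group_map)

  n_sites <- length(unique(filtered$pos))
  density <- category_density_table(
    c(all = n_sites), c(all = chrom_length), chrom_length)

  diversity <- window_diversity(filtered, config$div_window,
                                n = config$n_chromosomes,
                                chrom_length = chrom_length)
  hetw <- window_diversity(filtered, config$het_window,
                           n = config$n_chromosomes,
                           chrom_length = chrom_length)

  regions <- sweep_scan(filtered, config$hmm)
  sharing <- if (nrow(regions))
    classify_sharing(regions, config$group_map) else NULL
  shared_stats <- if (nrow(regions))
    shared_length_stats(regions, config$group_map) else NULL
  hard <- if (!is.null(sharing))
    hard_sweep_candidates(sharing, hetw, config$hard_rule) else NULL

  groups <- unique(config$group_map)
  es_col <- "experiment_specific"
  focal <- patterns[patterns[[es_col]] %in% TRUE, pos]
  clustering <- if (length(focal) >= 2) {
    cluster_permutation_test(focal, unique(filtered$pos),
                             R = config$perm_R,
                             seed = derive_seed(config$seed, 14L))
  } else NULL

  mk <- if (!is.null(inputs$gene_set)) mk_table(inputs$gene_set) else NULL

  summary <- list(
    seed = config$seed,
    n_input_records = nrow(counts),
    n_sites_pass = n_sites,
    n_experiment_specific = sum(patterns[[es_col]] %in% TRUE),
    n_single_line_discordant =
      sum(!is.na(patterns$single_line_discordant)),
    n_sweep_regions_per_line = if (nrow(regions))
      as.list(table(regions$line)) else list(),
    shared_bp = if (!is.null(shared_stats))
      as.list(setNames(shared_stats$total_shared$shared_bp,
                       shared_stats$total_shared$group)) else list(),
    shared_ratio = if (!is.null(shared_stats)) {
      if (is.finite(shared_stats$ratio)) shared_stats$ratio else "Inf"
    } else NA,
    n_hard_candidates = if (!is.null(hard)) nrow(hard) else 0L,
    clustering_p = if (!is.null(clustering)) clustering$p.value else NA,
    mk_significant = if (!is.null(mk))
      mk$gene[!is.na(mk$p) & mk$p < 0.05] else character(0),
    kaks_gt1 = if (!is.null(mk)) mk$gene[mk$kaks_gt1 %in% TRUE]
      else character(0))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    fw <- function(x, f) if (!is.null(x))
      fwrite(x, file.path(config$out_dir, f), sep = "\t")
    fw(patterns, "patterns.tsv")
    fw(density, "density.tsv")
    fw(diversity, "diversity.tsv")
    fw(hetw, "heterozygosity.tsv")
    if (nrow(regions)) {
      bed <- regions[, .(chrom, start, end, name = line,
                         score = round(mean_posterior * 1000))]
      fwrite(bed, file.path(config$out_dir, "sweeps.bed"), sep = "\t",
             col.names = FALSE)
    }
    fw(sharing, "sharing.tsv")
    fw(hard, "hard_candidates.tsv")
    fw(mk, "mk_table.tsv")
    jsonlite::write_json(summary,
                         file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = 10)
  }
  invisible(list(filtered = filtered, patterns = patterns,
                 density = density, diversity = diversity,
                 het_windows = hetw, regions = regions, sharing = sharing,
                 shared_stats = shared_stats, hard_candidates = hard,
                 clustering = clustering, mk = mk, summary = summary,
                 fixture = fixture))
}
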