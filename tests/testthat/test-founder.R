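test_that("founder panels follow the neutral 1/j spectrum and are reproducible", {
  p <- gen_founder_panel(205, 10000, 2e7, seed = 1)
  expect_s3_class(p, "haplotype_panel")
  expect_true(all(diff(p$positions) > 0))
  expect_true(all(p$positions >= 0 & p$positions < 2e7))
  counts <- colSums(p$alleles)
  expect_true(all(counts >= 1 & counts <= 204))
  # chi-square goodness of fit against expected multinomial 1/j counts
  probs <- (1 / (1:204)) / sum(1 / (1:204))
  obs <- tabulate(counts, nbins = 204)
  gof <- suppressWarnings(chisq.test(obs, p = probs))
  expect_gt(gof$p.value, 0.01)
  # determinism: bit-identical on repeat
  p2 <- gen_founder_panel(205, 10000, 2e7, seed = 1)
  expect_identical(p$alleles, p2$alleles)
  expect_identical(p$positions, p2$positions)
  # different seed differs
  p3 <- gen_founder_panel(205, 10000, 2e7, seed = 2)
  expect_false(identical(p$alleles, p3$alleles))
})

test_that("degenerate and invalid panel requests are handled", {
  empty <- gen_founder_panel(4, 0, 1000, seed = 7)
  expect_equal(empty$n_haplotypes, 4)
  expect_length(empty$positions, 0)
  expect_error(gen_founder_panel(10, 2000, 1000, seed = 1),
               "exceeds chrom_length")
  expect_error(haplotype_panel("c", 100, c(5, 5), matrix(0:1, 2, 2)),
               "strictly increasing")
  expect_error(haplotype_panel("c", 100, c(5, 150), matrix(0:1, 2, 2)),
               "positions")
})

test_that("LD-block panels keep positions and allele coding valid", {
  p <- gen_founder_panel(50, 500, 1e6, seed = 3, ld_blocks = 4)
  expect_true(all(p$alleles %in% 0:1))
  expect_true(all(diff(p$positions) > 0))
})

test_that("sweep spiking collapses heterozygosity only inside the region", {
  p <- gen_founder_panel(40, 400, 1e6, seed = 5)
  f0 <- matrix(rep(panel_freqs(p), each = 6), 6,
               dimnames = list(paste0("L", 1:6), NULL))
  reg <- c(2e5, 4e5)
  inreg <- p$positions >= reg[1] & p$positions < reg[2]

  hard <- spike_sweep(f0, p$positions, reg, "hard", "L2", panel = p,
                      seed = 11)
  het <- 2 * hard * (1 - hard)
  expect_lte(mean(het["L2", inreg]), 0.02)
  expect_identical(hard[, !inreg], f0[, !inreg])
  expect_identical(hard[c("L1", "L3", "L4", "L5", "L6"), ],
                   f0[c("L1", "L3", "L4", "L5", "L6"), ])

  soft <- spike_sweep(f0, p$positions, reg, "soft", c("L1", "L2", "L3"),
                      panel = p, seed = 12)
  expect_identical(soft["L1", inreg], soft["L2", inreg])
  expect_identical(soft["L1", inreg], soft["L3", inreg])
  expect_identical(soft[, !inreg], f0[, !inreg])

  expect_error(spike_sweep(f0, p$positions, c(100, 100), "hard", "L1"),
               "empty region")
  expect_error(spike_sweep(f0, p$positions, reg, "hard", "L9"),
               "unknown replicate")
  expect_error(spike_sweep(f0, p$positions, reg, "hard", c("L1", "L2")),
               "exactly one")
  expect_error(spike_sweep(f0, p$positions, reg, "soft", "L1"),
               "at least two")
})

test_that("pooled read sampling is unbiased and respects edge cases", {
  cfg0 <- pool_sampling_config(mean_coverage = 0, seed = 1)
  t0 <- sample_pool_counts(rep(0.5, 100), cfg0)
  expect_true(all(t0$depth == 0))
  expect_true(all(t0$missing))

  cfg <- pool_sampling_config(mean_coverage = 35, seed = 2)
  t1 <- sample_pool_counts(rep(1, 200), cfg)
  expect_identical(t1$alt_count, t1$depth)

  t2 <- sample_pool_counts(rep(0.3, 1e4), cfg)
  phat <- sum(t2$alt_count) / sum(t2$depth)
  se <- sqrt(0.3 * 0.7 / sum(t2$depth))
  expect_lt(abs(phat - 0.3), 3 * se)
  expect_true(all(t2$alt_count >= 0 & t2$alt_count <= t2$depth))

  expect_error(pool_sampling_config(mean_coverage = -1))
  expect_error(pool_sampling_config(error_rate = 0.5))
})

test_that("sequencing error shifts the alternate-read probability as p(1-e)+(1-p)e", {
  cfg <- pool_sampling_config(mean_coverage = 40, error_rate = 0.01,
                              seed = 9)
  tt <- sample_pool_counts(rep(0, 2e4), cfg)
  phat <- sum(tt$alt_count) / sum(tt$depth)
  se <- sqrt(0.01 * 0.99 / sum(tt$depth))
  expect_lt(abs(phat - 0.01), 4 * se)
})

test_that("panel and pool tables round-trip through TSV and VCF", {
  p <- gen_founder_panel(12, 50, 1e5, seed = 8)
  tsv <- tempfile(fileext = ".tsv")
  write_panel_tsv(p, tsv)
  p2 <- read_panel_tsv(tsv)
  expect_equal(p2$positions, p$positions)
  expect_equal(unname(p2$alleles), unname(p$alleles))
  expect_equal(p2$length_bp, p$length_bp)

  vcf <- tempfile(fileext = ".vcf")
  write_panel_vcf(p, vcf)
  p3 <- read_panel_vcf(vcf)
  expect_equal(p3$positions, p$positions)
  expect_equal(unname(p3$alleles), unname(p$alleles))

  pool <- sample_pool_counts(panel_freqs(p), pool_sampling_config(seed = 1),
                             positions = p$positions)
  pf <- tempfile(fileext = ".tsv.gz")
  write_pool_tsv(pool, pf)
  expect_equal(read_pool_tsv(pf)$alt_count, pool$alt_count)
})

test_that("multi-sample variant VCFs load as pooled records", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=1000>",
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Quality">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "L1", "L2", sep = "\t"),
    paste("chr1", "101", ".", "A", "T", ".", "PASS", ".", "AD:DP:GQ",
          "30,5:35:60", "0,40:40:55", sep = "\t"),
    paste("chr1", "202", ".", "G", "C,T", ".", "PASS", ".", "AD:DP:GQ",
          "20,10:30:50", "25,5:30:45", sep = "\t")), vcf)
  rec <- read_variant_vcf(vcf)
  expect_equal(nrow(rec), 4L)
  expect_equal(rec[rec$line == "L1" & rec$pos == 100, ]$alt_count, 5L)
  expect_equal(rec[rec$line == "L2" & rec$pos == 100, ]$depth, 40L)
  expect_equal(unique(rec[rec$pos == 201, ]$n_alleles), 3L)
  # triallelic row is droppable by the standard filter
  filt <- filter_variants(rec, filter_config())
  expect_false(201 %in% filt$pos)
})

test_that("simulation configs load from YAML", {
  yml <- tempfile(fileext = ".yaml")
  writeLines(c(
    "schedule:",
    "  - {gens: 5, N: 100, select: false}",
    "  - {gens: 48, N: 200, select: true}",
    "recomb_rate: 2",
    "recomb_units: cM_per_Mb",
    "selected_site: {pos: 500000, p0: 0.0025, w: [0.2, 2.1, 4.0]}",
    "final_sample: 100",
    "seed: 9"), yml)
  cfg <- sim_config_yaml(yml)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$schedule$N, c(100, 200))
  expect_equal(cfg$selected_site$w, c(0.2, 2.1, 4.0))
  expect_equal(cfg$seed, 9L)
})
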