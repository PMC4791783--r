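test_that("quality, depth, indel-proximity and biallelic filters apply", {
  gm <- six_line_map()
  pos <- c(50L, 92L, 110L, 111L, 300L, 400L)
  freqs <- lapply(gm, function(g) rep(0.5, length(pos)))
  names(freqs) <- names(gm)
  rec <- make_records(pos, freqs)
  # drop gq below threshold at pos 300 in one line only
  rec[pos == 300 & line == "S2", gq := 25]
  # mark pos 400 triallelic
  rec[, n_alleles := ifelse(pos == 400, 3L, 2L)]
  indels <- data.table::data.table(chrom = "chr1", start = 100L, end = 101L)

  out <- filter_variants(rec, filter_config(), indels = indels)
  kept <- sort(unique(out$pos))
  # 92 is 8 bp from the indel base (removed), 110 is 10 bp (removed,
  # inclusive rule), 111 is 11 bp (kept)
  expect_false(92 %in% kept)
  expect_false(110 %in% kept)
  expect_true(111 %in% kept)
  expect_false(300 %in% kept)   # gq 25 in one line
  expect_false(400 %in% kept)   # triallelic
  expect_true(50 %in% kept)

  # idempotence
  out2 <- filter_variants(out, filter_config(), indels = indels)
  expect_equal(out2$pos, out$pos)
  expect_equal(out2$status, out$status)

  # malformed counts error names the site
  bad <- data.table::copy(rec)[1, alt_count := depth + 5L]
  expect_error(filter_variants(bad, filter_config()), "chr1:50")
})

test_that("depth bounds remove whole sites", {
  gm <- six_line_map()
  rec <- make_records(c(10L, 20L, 30L),
                      lapply(setNames(nm = names(gm)),
                             function(x) rep(0.4, 3)))
  rec[pos == 10 & line == "C1", `:=`(depth = 5L, ref_count = 3L,
                                     alt_count = 2L)]
  rec[pos == 20 & line == "C2", `:=`(depth = 300L, ref_count = 180L,
                                     alt_count = 120L)]
  out <- filter_variants(rec, filter_config())
  expect_equal(sort(unique(out$pos)), 30L)
})

test_that("fixation status uses strict 99 % thresholds", {
  cfg <- filter_config()
  # reference fraction 0.995 -> alt 0.005 -> fixed for reference
  expect_equal(fixation_status(0.005, cfg), "fixed_ref")
  expect_equal(fixation_status(0.995, cfg), "fixed_alt")
  expect_equal(fixation_status(0.5, cfg), "polymorphic")
  # boundary: reference fraction exactly 0.99 is NOT fixed
  expect_equal(fixation_status(0.01, cfg), "polymorphic")
  expect_equal(fixation_status(0.99, cfg), "polymorphic")
  expect_equal(fixation_status(NA_real_, cfg), "missing")
})

test_that("site patterns flag experiment-specific and discordant sites", {
  gm <- six_line_map()
  pos <- c(1L, 2L, 3L, 4L)
  f <- list(
    S1 = c(1,    1, 0.5, 1),
    S2 = c(1,    1, 1,   1),
    S3 = c(1,    1, 1,   1),
    C1 = c(0,    1, 0,   1),
    C2 = c(0,    1, 0,   1),
    C3 = c(0,    1, 0,   0))
  rec <- make_records(pos, f, depth = 100)
  filt <- filter_variants(rec, filter_config())
  pat <- scan_site_patterns(filt, gm)
  pat <- pat[order(pos)]
  # site 1: selection fixed alt, control fixed ref -> experiment specific
  expect_true(pat$experiment_specific[1])
  expect_true(pat$group_fixed_selection[1])
  expect_true(pat$group_fixed_control[1])
  # site 2: all fixed same allele -> group fixed both, not specific
  expect_false(pat$experiment_specific[2])
  expect_true(pat$group_fixed_selection[2])
  # site 3: S1 polymorphic -> no group flag for selection
  expect_false(pat$group_fixed_selection[3])
  # site 4: five lines fixed alt, C3 fixed ref -> discordant line C3
  expect_equal(pat$single_line_discordant[4], "C3")
  expect_true(is.na(pat$single_line_discordant[1]))
})

test_that("missing calls null out the pattern flags", {
  gm <- six_line_map()
  rec <- make_records(1L, lapply(setNames(nm = names(gm)),
                                 function(x) 1))
  rec[line == "C3", `:=`(depth = 0L, ref_count = 0L, alt_count = 0L)]
  rec[, freq := ifelse(depth > 0, alt_count / depth, NA_real_)]
  rec[, status := fixation_status(freq)]
  pat <- scan_site_patterns(rec, gm)
  expect_true(is.na(pat$experiment_specific[1]))
  expect_true(is.na(pat$group_fixed_control[1]))
})

test_that("experiment-specific set equals the opposite-fixation intersection", {
  gm <- six_line_map()
  set.seed(42)
  pos <- seq_len(300)
  f <- lapply(setNames(nm = names(gm)), function(x)
    sample(c(0, 1, 0.5, 0.98, 0.02), 300, replace = TRUE))
  rec <- make_records(pos, f, depth = 100)
  filt <- filter_variants(rec, filter_config())
  pat <- scan_site_patterns(filt, gm)
  wide <- data.table::dcast(filt, pos ~ line, value.var = "status")
  sel_cols <- c("S1", "S2", "S3"); ctl_cols <- c("C1", "C2", "C3")
  manual <- wide[, {
    sa <- unlist(.SD[, sel_cols, with = FALSE])
    ca <- unlist(.SD[, ctl_cols, with = FALSE])
    .(es = (all(sa == "fixed_alt") & all(ca == "fixed_ref")) |
        (all(sa == "fixed_ref") & all(ca == "fixed_alt")))
  }, by = pos]
  merged <- merge(pat, manual, by = "pos")
  expect_equal(merged$experiment_specific, merged$es)
})

test_that("density table arithmetic matches the per-Kb definition", {
  tab <- category_density_table(c(all = 0L), c(all = 1e6))
  expect_equal(tab[tab$category == "all", ]$density_per_kb, 0.00)
  expect_error(category_density_table(c(a = 5L), c(a = 0)),
               "zero coverage")
  tab2 <- category_density_table(c(a = 1000L, b = 3000L),
                                 c(a = 1e6, b = 1e6))
  expect_equal(tab2$density_per_kb[1:2], c(1.00, 3.00))
  expect_equal(tab2$percent[1:2], c(25.00, 75.00))
  expect_equal(sum(tab2$percent[1:2]), 100)
})

test_that("enrichment Fisher test is symmetric and exact", {
  expect_equal(enrichment_fisher(1, 10, 1, 10)$p.value, 1.0)
  a <- enrichment_fisher(20, 100, 5, 80)$p.value
  b <- enrichment_fisher(5, 80, 20, 100)$p.value
  expect_equal(a, b, tolerance = 1e-12)
  # the 2x4 vs 22x22 coding table
  expect_equal(round(enrichment_fisher(2, 4, 22, 22)$p.value, 4), 0.0185)
  expect_error(enrichment_fisher(1, 0, 1, 10), "positive")
})

test_that("in-package Fisher agrees with stats::fisher.test on small tables", {
  set.seed(7)
  for (i in 1:25) {
    cells <- sample(0:15, 4, replace = TRUE)
    if (sum(cells[1:2]) == 0 || sum(cells[3:4]) == 0) next
    ours <- fisher_exact_2x2(cells[1], cells[2], cells[3], cells[4])$p.value
    ref <- stats::fisher.test(matrix(cells, 2, byrow = TRUE))$p.value
    expect_equal(ours, ref, tolerance = 1e-9)
  }
})
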