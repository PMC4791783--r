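test_that("sharing classes follow the coverage definitions", {
  gm <- six_line_map()
  reg <- data.table::data.table(
    chrom = "c",
    start = c(rep(100L, 3), rep(5000L, 6), 9000L),
    end = c(rep(900L, 3), rep(6000L, 6), 9500L),
    line = c("S1", "S2", "S3", names(gm), "C2"))
  cl <- classify_sharing(reg, gm)
  expect_equal(unique(cl[cl$start == 100]$class), "group_shared")
  expect_equal(unique(cl[cl$start == 5000]$class), "all_shared")
  expect_equal(cl[cl$start == 9000]$class, "line_specific")
})

test_that("sharing classification matches a brute-force per-bp scan", {
  gm <- six_line_map()
  set.seed(31)
  for (rep in 1:5) {
    rows <- list()
    for (ln in names(gm)) {
      k <- sample(1:4, 1)
      starts <- sort(sample(seq(0, 9e4, by = 100), k))
      widths <- sample(seq(500, 8000, by = 100), k)
      ir <- IRanges::reduce(IRanges::IRanges(starts + 1, starts + widths))
      rows[[ln]] <- data.table::data.table(
        chrom = "c", start = IRanges::start(ir) - 1L,
        end = pmin(IRanges::end(ir), 1e5), line = ln)
    }
    reg <- data.table::rbindlist(rows)
    cl <- classify_sharing(reg, gm)
    want <- brute_sharing(as.data.frame(reg), gm, 1e5)
    for (ln in names(gm)) {
      got <- tapply(cl[cl$line == ln]$end - cl[cl$line == ln]$start,
                    factor(cl[cl$line == ln]$class,
                           levels = c("all_shared", "group_shared",
                                      "line_specific", "other")),
                    sum)
      got[is.na(got)] <- 0
      expect_equal(as.numeric(got), as.numeric(want[[ln]]))
      # conservation: classified lengths cover the line's input exactly
      expect_equal(sum(cl[cl$line == ln]$end - cl[cl$line == ln]$start),
                   sum(reg[reg$line == ln]$end - reg[reg$line == ln]$start))
    }
  }
})

test_that("overlapping regions within one line are rejected", {
  gm <- six_line_map()
  reg <- data.table::data.table(chrom = "c",
                                start = c(100L, 500L),
                                end = c(800L, 900L),
                                line = "S1")
  expect_error(classify_sharing(reg, gm), "overlapping")
})

test_that("shared-length statistics and ratios", {
  gm <- six_line_map()
  mk <- function(s, e, lines) data.table::data.table(
    chrom = "chr2L", start = s, end = e, line = lines)
  reg <- rbind(mk(0L, 1200L, c("S1", "S2", "S3")),
               mk(5000L, 5100L, c("C1", "C2", "C3")))
  st <- shared_length_stats(reg, gm, ratio_groups = c("selection",
                                                      "control"))
  expect_equal(st$total_shared[st$total_shared$group == "selection",
                               ]$shared_bp, 1200)
  expect_equal(st$ratio, 12.0)
  expect_false(st$ratio_infinite)

  # identical region sets give ratio 1
  reg2 <- rbind(mk(0L, 1000L, names(gm)))
  st2 <- shared_length_stats(reg2, gm)
  expect_equal(st2$ratio, 1.0)

  # empty control shared set flags infinity without error
  reg3 <- rbind(mk(0L, 1000L, c("S1", "S2", "S3")),
                mk(2000L, 3000L, "C1"))
  st3 <- shared_length_stats(reg3, gm, c("selection", "control"))
  expect_true(st3$ratio_infinite)
})

test_that("hard-sweep candidates respect both heterozygosity and isolation", {
  gm <- six_line_map()
  cl <- data.table::data.table(
    chrom = "c",
    start = c(100000L, 400000L, 700000L, 2000000L),
    end = c(150000L, 450000L, 750000L, 2100000L),
    line = c("S1", "S1", "S1", "S2"),
    class = c("line_specific", "line_specific", "line_specific",
              "group_shared"))
  hw <- data.table::data.table(
    chrom = "c",
    line = rep(c("S1", "S2"), each = 30),
    start = rep(seq(0L, 2900000L, by = 100000L), 2),
    end = rep(seq(100000L, 3000000L, by = 100000L), 2),
    H = 0.2)
  # region 1: low het, isolated -> candidate
  hw[line == "S1" & start == 100000L, H := 0.005]
  # region 2: high het -> rejected
  hw[line == "S1" & start == 400000L, H := 0.10]
  # region 3: low het but 10 kb case handled below
  hw[line == "S1" & start == 700000L, H := 0.005]
  cand <- hard_sweep_candidates(cl, hw, hard_sweep_rule())
  expect_true(100000L %in% cand$start)
  expect_false(400000L %in% cand$start)
  expect_true(700000L %in% cand$start)  # 1.25 Mb from shared: isolated

  # move the shared region to 10 kb away from region 3 -> rejected
  cl2 <- data.table::copy(cl)
  cl2[4, `:=`(start = 760000L, end = 800000L)]
  cand2 <- hard_sweep_candidates(cl2, hw, hard_sweep_rule())
  expect_false(700000L %in% cand2$start)

  # regions without heterozygosity data warn and are skipped
  cl3 <- data.table::data.table(chrom = "c", start = 0L, end = 1000L,
                                line = "S3", class = "line_specific")
  expect_warning(hard_sweep_candidates(cl3, hw, hard_sweep_rule()),
                 "skipped")
})

test_that("clustering permutation test: tight packing, errors, shift invariance", {
  background <- c(0:9, seq(1000, 2e6, by = 1000))
  res <- cluster_permutation_test(0:9, background, R = 999, seed = 5)
  expect_equal(res$p.value, 1 / 1000)

  expect_error(cluster_permutation_test(5, background, R = 99),
               "at least two")
  expect_error(cluster_permutation_test(c(1, 500), background, R = 99),
               "subset")

  shifted <- cluster_permutation_test(0:9 + 777, background + 777,
                                      R = 999, seed = 5)
  expect_equal(shifted$p.value, res$p.value)
})
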