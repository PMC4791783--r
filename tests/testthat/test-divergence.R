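test_that("group consensus substitutes fixed alternates, strand-aware", {
  cds <- "ATGAAATTT"
  genome_plus <- list(chr = paste0("CCCCC", cds, "GGGGG"))
  gene <- data.frame(chrom = "chr", start = 5L, end = 14L, strand = "+",
                     gene_id = "g")
  expect_equal(group_consensus_cds(gene, NULL, genome_plus), cds)
  # one fixed alternate inside the CDS changes exactly one base
  fixed <- data.frame(pos = 8L, alt = "G")
  got <- group_consensus_cds(gene, fixed, genome_plus)
  expect_equal(got, "ATGGAATTT")
  expect_equal(sum(strsplit(got, "")[[1]] != strsplit(cds, "")[[1]]), 1L)

  # minus strand: genomic span holds revcomp(cds); a genomic substitution
  # appears complemented in the returned coding sequence
  genomic <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  genome_minus <- list(chr = paste0("CCCCC", genomic, "GGGGG"))
  gene_m <- data.frame(chrom = "chr", start = 5L, end = 14L, strand = "-",
                       gene_id = "gm")
  expect_equal(group_consensus_cds(gene_m, NULL, genome_minus), cds)
  # coding offset 1 (second base of ATG) sits at genomic pos
  # 5 + (9 - 1 - 1) = 12; a genomic "C" reads as G on the coding strand:
  # ATG -> AGG
  fixed_m <- data.frame(pos = 12L, alt = "C")
  expect_equal(group_consensus_cds(gene_m, fixed_m, genome_minus),
               "AGGAAATTT")

  bad <- data.frame(chrom = "chr", start = 5L, end = 13L, strand = "+",
                    gene_id = "gbad")
  expect_error(group_consensus_cds(bad, NULL, genome_plus), "gbad")
})

test_that("MK counting classifies fixed differences and polymorphisms", {
  # identical consensuses, no variants: all zeros
  z <- mk_counts("ATGAAATTT", "ATGAAATTT")
  expect_equal(unlist(z[c("DS", "DN", "PS", "PN")]),
               c(DS = 0L, DN = 0L, PS = 0L, PN = 0L))
  # one synonymous fixed difference only: AAA -> AAG (Lys)
  s <- mk_counts("ATGAAATTT", "ATGAAGTTT")
  expect_equal(unlist(s[c("DS", "DN", "PS", "PN")]),
               c(DS = 1L, DN = 0L, PS = 0L, PN = 0L))
  # a site both divergent and polymorphic counts as polymorphism only
  v <- data.frame(codon = 2L, codon_pos = 3L, alt = "G",
                  group = "control")
  both <- mk_counts("ATGAAATTT", "ATGAAGTTT", variants = v)
  expect_equal(both$DS, 0L)
  expect_equal(both$PS, 1L)
  expect_error(mk_counts("ATGAAA", "ATGAAATTT"), "mismatch")
})

test_that("MK round-trip identity holds over random targets", {
  set.seed(17)
  for (i in 1:10) {
    tg <- data.frame(DS = sample(0:5, 1), DN = sample(0:5, 1),
                     PS = sample(0:10, 1), PN = sample(0:10, 1))
    gs <- gen_mk_gene_set(1, 60, tg, seed = 1000 + i)
    got <- count_mk_gene_set(gs)
    expect_equal(unlist(got[, c("DS", "DN", "PS", "PN")]),
                 unlist(tg), ignore_attr = TRUE)
  }
})

test_that("DoS reproduces the verified per-gene values", {
  expect_equal(dos(2, 2, 22, 0), 0.5)
  expect_equal(round(dos(1, 2, 14, 0), 4), 0.6667)
  expect_equal(dos(4, 1, 0, 4), -0.8)
  expect_true(is.na(dos(0, 0, 5, 5)))
  expect_true(is.na(dos(2, 2, 0, 0)))
})

test_that("MK Fisher p-values are exact and handle zero margins", {
  expect_equal(round(mkt_fisher(3, 2, 21, 0), 4), 0.0308)
  expect_equal(round(mkt_fisher(15, 0, 6, 3), 4), 0.0415)
  expect_equal(mkt_fisher(1, 1, 1, 1), 1.0)
  expect_equal(mkt_fisher(0, 0, 5, 5), 1)
  expect_equal(mkt_fisher(5, 5, 0, 0), 1)
})

test_that("Nei-Gojobori counts potential sites and pathways correctly", {
  # identical sequences
  same <- nei_gojobori("ATGAAATTT", "ATGAAATTT")
  expect_equal(same$Nd, 0)
  expect_equal(same$Sd, 0)
  expect_equal(same$dN, 0)
  expect_equal(same$dS, 0)
  expect_true(is.na(same$ratio))

  # single codon TTT vs TTA: the fully worked example
  r <- nei_gojobori("TTT", "TTA")
  expect_equal(r$S, 0.5, tolerance = 1e-12)
  expect_equal(r$N, 2.5, tolerance = 1e-12)
  expect_equal(r$Sd, 0)
  expect_equal(r$Nd, 1)
  expect_equal(r$pN, 0.4, tolerance = 1e-12)
  expect_equal(r$dN, -0.75 * log(1 - 4 / 3 * 0.4), tolerance = 1e-12)
  expect_equal(r$dS, 0)
  expect_true(is.na(r$ratio))

  # synonymous third-position change: GGA -> GGG (Gly); CTG companions
  # supply enough synonymous site capacity for the JC correction
  r2 <- nei_gojobori("GGACTGCTG", "GGGCTGCTG")
  expect_equal(r2$Nd, 0)
  expect_equal(r2$Sd, 1)
  expect_equal(r2$dN, 0)
  expect_gt(r2$dS, 0)
  expect_equal(r2$ratio, 0)

  # saturated synonymous proportion: correction undefined
  expect_error(nei_gojobori("GGAATG", "GGGATG"), "undefined")
  expect_error(nei_gojobori("ATGA", "ATGC"), "divisible")
  expect_error(nei_gojobori("ATN", "ATG"), "ambiguity")
})

test_that("Nei-Gojobori is symmetric and conserves N + S", {
  set.seed(23)
  for (i in 1:10) {
    pair <- mutate_cds_neutral(40, 10, seed = 300 + i)
    a <- nei_gojobori(pair$seqA, pair$seqB)
    b <- nei_gojobori(pair$seqB, pair$seqA)
    expect_equal(a$dN, b$dN, tolerance = 1e-12)
    expect_equal(a$dS, b$dS, tolerance = 1e-12)
    expect_equal(a$N + a$S, 3 * 40, tolerance = 1e-9)
  }
})

test_that("the gene-set MK table carries DoS, p and Ka/Ks columns", {
  gs <- gen_mk_gene_set(2, 80, data.frame(DS = c(2, 0), DN = c(2, 2),
                                          PS = c(22, 20), PN = c(0, 0)),
                        seed = 9)
  tab <- mk_table(gs)
  expect_equal(tab$DoS, c(0.5, 1), tolerance = 1e-12)
  expect_equal(round(tab$p, 4), c(0.0185, 0.0043))
  expect_true(all(is.finite(tab$Ka)))
})
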