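#' Annotate the functional effect of SNPs
#'
#' Classifies each site into `cds_synonymous`, `cds_nonsynonymous`, `utr5`,
#' `utr3`, `intron`, `ncRNA` or `intergenic`. Coding sites are classified by
#' translating the reference and mutant codon, strand-aware and splice-aware
#' across multi-interval CDS. Overlapping features resolve by the fixed
#' precedence `cds > utr5 > utr3 > intron > ncRNA`; positions inside a gene
#' span but in no listed feature are introns; everything else is
#' intergenic.
#'
#' @param sites data.table with `chrom, pos` (0-based), `ref`, `alt`
#'   (single bases, plus strand of the genome).
#' @param models Gene models as from [read_gff3()]: `chrom, start, end,
#'   strand, type, gene_id` with types among `gene, CDS, utr5, utr3,
#'   ncRNA` (GFF3 `five_prime_UTR`/`three_prime_UTR` accepted).
#' @param genome Named character vector of chromosome sequences.
#' @return `sites` with added `effect` (factor over the seven categories)
#'   and `gene_id` columns.
#' @export
annotate_effect <- function(sites, models, genome) {
  sites <- as.data.table(sites)
  models <- as.data.table(models)
  models[, type := normalize_feature_type(type)]
  cds <- models[type == "cds"]
  # validate CDS frames up front, naming the offending gene
  if (nrow(cds)) {
    bad <- cds[, .(len = sum(end - start)), by = gene_id][len %% 3 != 0]
    if (nrow(bad))
      stop("CDS length not divisible by 3 for gene ", bad$gene_id[1])
  }
  site_gr <- GenomicRanges::GRanges(
    sites$chrom, IRanges::IRanges(sites$pos + 1L, width = 1L))
  effect <- rep("intergenic", nrow(sites))
  gene_hit <- rep(NA_character_, nrow(sites))
  assign_hits <- function(feature_dt, label) {
    if (!nrow(feature_dt)) return()
    gr <- GenomicRanges::GRanges(
      feature_dt$chrom,
      IRanges::IRanges(feature_dt$start + 1L, feature_dt$end))
    ov <- GenomicRanges::findOverlaps(site_gr, gr, select = "first")
    hit <- !is.na(ov) & effect == "intergenic"
    effect[hit] <<- label
    gene_hit[hit] <<- feature_dt$gene_id[ov[hit]]
  }
  # precedence order: assign most specific first, never overwrite
  assign_hits(cds, "cds")
  assign_hits(models[type == "utr5"], "utr5")
  assign_hits(models[type == "utr3"], "utr3")
  assign_hits(models[type == "gene"], "intron")
  assign_hits(models[type == "ncrna"], "ncRNA")
  # classify coding sites by codon translation
  is_cds <- which(effect == "cds")
  for (i in is_cds) {
    cls <- classify_cds_site(sites$chrom[i], sites$pos[i],
                             sites$ref[i], sites$alt[i],
                             cds[gene_id == gene_hit[i]], genome)
    effect[i] <- cls
  }
  sites[, effect := factor(effect, levels = c(
    "intergenic", "utr5", "cds_synonymous", "cds_nonsynonymous",
    "intron", "utr3", "ncRNA"))]
  sites[, gene_id := gene_hit]
  sites[]
}

normalize_feature_type <- function(type) {
  t <- tolower(type)
  t[t %in% c("five_prime_utr", "5utr", "utr5")] <- "utr5"
  t[t %in% c("three_prime_utr", "3utr", "utr3")] <- "utr3"
  t[t %in% c("ncrna", "nc_rna")] <- "ncrna"
  t[t == "cds"] <- "cds"
  t
}

# synonymous/non-synonymous call for one site inside the CDS of one gene
classify_cds_site <- function(chrom, pos, ref, alt, gene_cds, genome) {
  gene_cds <- gene_cds[order(start)]
  strand <- gene_cds$strand[1]
  cds_seq <- group_consensus_cds(gene_cds, NULL, genome)
  # CDS-relative offset of the genomic position (coding strand)
  widths <- gene_cds$end - gene_cds$start
  iv <- which(pos >= gene_cds$start & pos < gene_cds$end)[1]
  off_plus <- sum(widths[seq_len(iv - 1L)]) + (pos - gene_cds$start[iv])
  total <- sum(widths)
  off <- if (strand == "-") total - 1L - off_plus else off_plus
  codon_idx <- off %/% 3L
  codon_pos <- off %% 3L + 1L
  codon <- substr(cds_seq, 3L * codon_idx + 1L, 3L * codon_idx + 3L)
  alt_base <- if (strand == "-") revcomp(alt) else toupper(alt)
  mut <- codon
  substr(mut, codon_pos, codon_pos) <- alt_base
  if (classify_codon_change(codon, mut) == "synonymous")
    "cds_synonymous" else "cds_nonsynonymous"
}
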