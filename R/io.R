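#' Write a haplotype panel as TSV
#'
#' Plain-text panel serialisation: one row per site, columns `chrom`, `pos`
#' (0-based) and one 0/1 column per haplotype. A `#length_bp=` comment line
#' records the chromosome length. Gzip output is selected by a `.gz` suffix.
#'
#' @param panel A [haplotype_panel()].
#' @param path Output path (`.tsv` or `.tsv.gz`).
#' @return `path`, invisibly.
#' @export
write_panel_tsv <- function(panel, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  writeLines(sprintf("#length_bp=%.0f", panel$length_bp), con)
  close(con)
  dt <- data.table(chrom = panel$chrom, pos = panel$positions)
  ap <- as.data.table(t(panel$alleles))
  setnames(ap, paste0("H", seq_len(panel$n_haplotypes)))
  fwrite(cbind(dt, ap), path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Read a haplotype panel from TSV
#' @param path Path written by [write_panel_tsv()].
#' @return A [haplotype_panel()].
#' @export
read_panel_tsv <- function(path) {
  lines <- readLines(path)  # transparently decompresses .gz
  len <- as.numeric(sub("#length_bp=", "", lines[1]))
  dt <- fread(text = lines[-1])
  alleles <- t(as.matrix(dt[, -(1:2)]))
  haplotype_panel(dt$chrom[1], len, dt$pos, alleles,
                  allow_monomorphic = TRUE)
}

#' Write a haplotype panel as VCF (haploid GT columns)
#'
#' Emits a minimal VCF 4.2 with one haploid sample column per haplotype,
#' REF/ALT fixed to A/T placeholder alleles, and 1-based positions.
#'
#' @param panel A [haplotype_panel()].
#' @param path Output path (`.vcf` or `.vcf.gz`).
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(panel, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%.0f>", panel$chrom,
                       panel$length_bp),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT",
                       paste0("H", seq_len(panel$n_haplotypes))),
                     collapse = "\t")), con)
  if (length(panel$positions)) {
    gt <- apply(panel$alleles, 2, paste, collapse = "\t")
    writeLines(paste(panel$chrom, panel$positions + 1L, ".", "A", "T", ".",
                     "PASS", ".", "GT", gt, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a haploid-GT VCF back into a haplotype panel
#' @param path VCF path as written by [write_panel_vcf()].
#' @return A [haplotype_panel()].
#' @export
read_panel_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ctg <- grep("^##contig", v@meta, value = TRUE)[1]
  len <- as.numeric(sub(".*length=([0-9]+).*", "\\1", ctg))
  gt <- vcfR::extract.gt(v, element = "GT")
  # haploid GT "0"/"1"; external panels may carry "." missing calls, which
  # are set heterozygous by convention (0.5 expected dosage rounds to ref)
  alleles <- t(matrix(suppressWarnings(as.integer(gt)), nrow(gt), ncol(gt)))
  alleles[is.na(alleles)] <- 0L
  haplotype_panel(v@fix[1, "CHROM"], len,
                  as.integer(v@fix[, "POS"]) - 1L, alleles,
                  allow_monomorphic = TRUE)
}

#' Write pooled site records as TSV
#' @param counts data.table from [sample_pool_counts()] (or same layout).
#' @param path Output path; `.gz` gzip-compresses.
#' @return `path`, invisibly.
#' @export
write_pool_tsv <- function(counts, path) {
  fwrite(counts, path, sep = "\t")
  invisible(path)
}

#' Read pooled site records from TSV
#' @param path Path written by [write_pool_tsv()].
#' @return data.table of pooled site records.
#' @export
read_pool_tsv <- function(path) {
  if (grepl("\\.gz$", path)) fread(text = readLines(path), sep = "\t")
  else fread(path, sep = "\t")
}

#' Write gene models as GFF3
#'
#' @param models data.frame with columns `chrom, start, end, strand, type,
#'   gene_id` (0-based half-open coordinates; converted to 1-based closed
#'   GFF3 on output).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  gr <- GenomicRanges::GRanges(
    models$chrom,
    IRanges::IRanges(models$start + 1L, models$end),
    strand = models$strand)
  S4Vectors::mcols(gr)$type <- models$type
  S4Vectors::mcols(gr)$ID <- paste0(models$gene_id, ":", models$type, ":",
                                    seq_len(nrow(models)))
  S4Vectors::mcols(gr)$Parent <- models$gene_id
  # CDS intervals are emitted in frame: phase 0
  S4Vectors::mcols(gr)$phase <- ifelse(toupper(models$type) == "CDS",
                                       0L, NA_integer_)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3
#' @param path GFF3 path.
#' @return data.frame with `chrom, start, end, strand, type, gene_id`
#'   (0-based half-open).
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  par <- S4Vectors::mcols(gr)$Parent
  if (methods::is(par, "List")) par <- vapply(par, function(x)
    if (length(x)) x[[1]] else NA_character_, character(1))
  data.table(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             type = as.character(S4Vectors::mcols(gr)$type),
             gene_id = as.character(par))
}

#' Write named sequences as FASTA
#' @param seqs Named character vector or `Biostrings::DNAStringSet`.
#' @param path Output path; `.gz` compresses.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (!methods::is(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read FASTA sequences
#' @param path FASTA path.
#' @return Named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Read a multi-sample variant VCF into pooled site records
#'
#' Extracts per-sample AD (ref,alt depths), DP and GQ from a VCF 4.2 and
#' returns the long per-line record table the pipeline consumes. Sites
#' with more than one alternate allele are flagged via `n_alleles` so the
#' biallelic filter can drop them.
#'
#' @param path VCF path (`.vcf` or `.vcf.gz`).
#' @return data.table with `chrom, pos` (0-based), `ref, alt, line,
#'   ref_count, alt_count, depth, gq, n_alleles`.
#' @export
read_variant_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ad <- vcfR::extract.gt(v, element = "AD")
  gq <- suppressWarnings(
    matrix(as.numeric(vcfR::extract.gt(v, element = "GQ")),
           nrow(ad), ncol(ad)))
  fix <- v@fix
  n_alleles <- 1L + lengths(strsplit(fix[, "ALT"], ","))
  rows <- lapply(colnames(ad), function(sm) {
    parts <- strsplit(ad[, sm], ",")
    rc <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1)))
    ac <- suppressWarnings(as.integer(vapply(parts, function(x)
      if (length(x) >= 2) x[2] else "0", "")))
    rc[is.na(rc)] <- 0L
    ac[is.na(ac)] <- 0L
    data.table(chrom = fix[, "CHROM"],
               pos = as.integer(fix[, "POS"]) - 1L,
               ref = fix[, "REF"],
               alt = sub(",.*", "", fix[, "ALT"]),
               line = sm,
               ref_count = rc, alt_count = ac,
               depth = rc + ac,
               gq = gq[, which(colnames(ad) == sm)],
               n_alleles = n_alleles)
  })
  rbindlist(rows)
}
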