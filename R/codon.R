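# Codon-level helpers shared by the effect annotator, the MK/Ka-Ks module
# and the synthetic gene-set generator. The code table is the standard
# genetic code as shipped by Biostrings.

.codon_env <- new.env(parent = emptyenv())

codon_code <- function() {
  if (is.null(.codon_env$aa)) {
    .codon_env$aa <- Biostrings::GENETIC_CODE
    .codon_env$sense <- names(.codon_env$aa)[.codon_env$aa != "*"]
  }
  .codon_env
}

#' Translate an in-frame CDS string to amino acids
#' @param cds Character scalar, length divisible by 3.
#' @return Character scalar of amino acids (`*` = stop).
#' @export
translate_cds <- function(cds) {
  if (nchar(cds) %% 3 != 0) stop("CDS length not divisible by 3")
  as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                     no.init.codon = TRUE))
}

# split a CDS into its codons
split_codons <- function(cds) {
  n <- nchar(cds) %/% 3L
  substring(cds, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

# amino acid of one codon
codon_aa <- function(codon) unname(codon_code()$aa[codon])

# all nine single-nucleotide mutants of a codon
codon_neighbors <- function(codon) {
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (p in 1:3) {
    for (b in setdiff(bases, substr(codon, p, p))) {
      mut <- codon
      substr(mut, p, p) <- b
      out <- c(out, mut)
    }
  }
  out
}

# classify a single-nucleotide codon change; mutations to stop codons are
# non-synonymous
classify_codon_change <- function(from, to) {
  stopifnot(nchar(from) == 3, nchar(to) == 3)
  if (from == to) return("none")
  if (codon_aa(from) == codon_aa(to)) "synonymous" else "nonsynonymous"
}

# fraction of synonymous one-step changes per position -> potential
# synonymous sites of a codon (Nei-Gojobori); stop neighbours count as
# non-synonymous opportunities
codon_syn_sites <- function(codon) {
  code <- codon_code()
  if (is.null(code$syn_sites)) {
    all64 <- names(code$aa)
    s <- setNames(numeric(64), all64)
    for (cd in all64) {
      aa0 <- code$aa[cd]
      tot <- 0
      for (p in 1:3) {
        muts <- vapply(setdiff(c("A", "C", "G", "T"), substr(cd, p, p)),
                       function(b) { m <- cd; substr(m, p, p) <- b; m },
                       character(1))
        tot <- tot + sum(code$aa[muts] == aa0) / 3
      }
      s[cd] <- tot
    }
    code$syn_sites <- s
  }
  unname(code$syn_sites[codon])
}

# reverse complement of a character DNA string
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
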