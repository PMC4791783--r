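#' Build a group consensus CDS from fixed genotypes
#'
#' Substitutes group-fixed alternate alleles into the reference and splices
#' the CDS of one gene, strand-aware: for minus-strand genes the returned
#' sequence is the reverse complement of the substituted genomic span.
#' Sites at which the group is not uniformly fixed are skipped with a
#' warning (flagged), matching the use of fixed genotypes only.
#'
#' @param gene One-row data.frame with `chrom, start, end, strand`
#'   (0-based half-open; single CDS interval) or a data.frame of multiple
#'   CDS intervals of one gene ordered by `start`.
#' @param fixed_sites data.frame with `pos` (0-based) and `alt` (base) of
#'   sites fixed for the alternate allele in every line of the group; pass
#'   zero rows for no substitutions.
#' @param reference Named character vector of chromosome sequences.
#' @return Character CDS (coding strand).
#' @export
group_consensus_cds <- function(gene, fixed_sites, reference) {
  gene <- as.data.frame(gene)
  chrom <- gene$chrom[1]
  strand <- gene$strand[1]
  refseq <- reference[[chrom]]
  if (is.null(refseq)) stop("reference lacks chromosome ", chrom)
  pieces <- character(nrow(gene))
  for (i in seq_len(nrow(gene))) {
    s <- gene$start[i]; e <- gene$end[i]
    piece <- substr(refseq, s + 1L, e)
    if (!is.null(fixed_sites) && nrow(fixed_sites)) {
      hit <- fixed_sites$pos >= s & fixed_sites$pos < e
      for (k in which(hit)) {
        off <- fixed_sites$pos[k] - s + 1L
        substr(piece, off, off) <- toupper(fixed_sites$alt[k])
      }
    }
    pieces[i] <- piece
  }
  cds <- paste(pieces, collapse = "")
  if (strand == "-") cds <- revcomp(cds)
  if (nchar(cds) %% 3 != 0)
    stop("CDS length not divisible by 3 for gene ",
         if (!is.null(gene$gene_id)) gene$gene_id[1] else "<unnamed>")
  cds
}

#' McDonald-Kreitman counts for one gene
#'
#' Counts fixed synonymous/non-synonymous differences (`DS`, `DN`) between
#' two group consensus CDS and synonymous/non-synonymous polymorphisms
#' (`PS`, `PN`) within the groups (pooled over both). Each differing
#' nucleotide is classified by toggling it alone in the codon context of
#' the first consensus. A site that is both divergent between consensuses
#' and polymorphic within a group is counted as polymorphism only.
#'
#' @param cons_a,cons_b Equal-length in-frame consensus CDS strings.
#' @param variants Optional data.frame of within-group polymorphisms with
#'   columns `codon` (1-based codon index), `codon_pos` (1-3), `alt`
#'   (alternate base, coding strand) and `group`.
#' @return List with `DS, DN, PS, PN`, plus `DoS` and Fisher `p.value`
#'   (NA where undefined).
#' @export
mk_counts <- function(cons_a, cons_b, variants = NULL) {
  if (nchar(cons_a) != nchar(cons_b)) stop("consensus length mismatch")
  if (nchar(cons_a) %% 3 != 0) stop("CDS length not divisible by 3")
  ca <- split_codons(cons_a)
  cb <- split_codons(cons_b)
  DS <- DN <- PS <- PN <- 0L
  poly_nt <- integer(0)  # nucleotide positions polymorphic within a group
  if (!is.null(variants) && nrow(variants)) {
    for (i in seq_len(nrow(variants))) {
      ci <- variants$codon[i]
      cp <- variants$codon_pos[i]
      poly_nt <- c(poly_nt, 3L * (ci - 1L) + cp)
      base_codon <- ca[ci]
      mut <- base_codon
      substr(mut, cp, cp) <- variants$alt[i]
      if (mut == base_codon) {
        # variant alt equals consensus A; classify against consensus B codon
        base_codon <- cb[ci]
        mut <- base_codon
        substr(mut, cp, cp) <- variants$alt[i]
      }
      cls <- classify_codon_change(base_codon, mut)
      if (cls == "synonymous") PS <- PS + 1L
      else if (cls == "nonsynonymous") PN <- PN + 1L
    }
  }
  diff_codon <- which(ca != cb)
  for (ci in diff_codon) {
    a <- ca[ci]; b <- cb[ci]
    pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    for (p in pos) {
      nt <- 3L * (ci - 1L) + p
      if (nt %in% poly_nt) next  # polymorphism takes precedence
      mut <- a
      substr(mut, p, p) <- substr(b, p, p)
      cls <- classify_codon_change(a, mut)
      if (cls == "synonymous") DS <- DS + 1L else DN <- DN + 1L
    }
  }
  p <- mkt_fisher(DS, DN, PS, PN)
  list(DS = DS, DN = DN, PS = PS, PN = PN,
       DoS = dos(DS, DN, PS, PN), p.value = p)
}

#' Direction of selection statistic
#'
#' `DoS = DN/(DN+DS) - PN/(PN+PS)`; positive values indicate an excess of
#' non-synonymous divergence (positive selection), negative values an
#' excess of non-synonymous polymorphism (weak negative selection).
#'
#' @param DS,DN,PS,PN Non-negative MK counts.
#' @return DoS in `[-1, 1]`, or `NA` when either denominator is zero.
#' @export
dos <- function(DS, DN, PS, PN) {
  if (DN + DS <= 0 || PN + PS <= 0) return(NA_real_)
  DN / (DN + DS) - PN / (PN + PS)
}

#' Two-sided Fisher exact p for an MK table
#'
#' Exact two-sided test on the 2x2 table `[[DS, DN], [PS, PN]]`. Tables
#' with a zero margin are uninformative and return `p = 1` by convention.
#'
#' @param DS,DN,PS,PN Non-negative MK counts.
#' @return Two-sided p-value.
#' @export
mkt_fisher <- function(DS, DN, PS, PN) {
  if ((DS + DN) == 0 || (PS + PN) == 0 ||
      (DS + PS) == 0 || (DN + PN) == 0) return(1)
  fisher_exact_2x2(DS, DN, PS, PN)$p.value
}

#' MK test table for a gene set
#'
#' Runs [mk_counts()] over every gene of a [gen_mk_gene_set()] gene set
#' (or any object with the same shape) and returns a per-gene table in the
#' layout `gene, DS, DN, PS, PN, DoS, p` plus Ka/Ks columns from
#' [nei_gojobori()] on the two consensuses and a `kaks_gt1` flag.
#'
#' @param gs A `gene_set`.
#' @return data.table, one row per gene.
#' @export
mk_table <- function(gs) {
  rows <- lapply(seq_len(nrow(gs$genes)), function(g) {
    id <- gs$genes$gene_id[g]
    v <- gs$variants[gs$variants$gene_id == id, ]
    mk <- mk_counts(gs$group_sequences$control[[id]],
                    gs$group_sequences$selection[[id]], variants = v)
    ng <- nei_gojobori(gs$group_sequences$control[[id]],
                       gs$group_sequences$selection[[id]])
    data.table(gene = id, DS = mk$DS, DN = mk$DN, PS = mk$PS, PN = mk$PN,
               DoS = mk$DoS, p = mk$p.value,
               Ka = ng$dN, Ks = ng$dS, KaKs = ng$ratio,
               kaks_gt1 = !is.na(ng$ratio) && ng$ratio > 1 ||
                 (is.na(ng$ratio) && ng$dN > 0))
  })
  rbindlist(rows)
}

#' Nei-Gojobori (approximate) Ka/Ks between two CDS
#'
#' Unweighted pathway counting: potential synonymous sites `S` per codon
#' are the per-position fractions of one-step changes that are synonymous
#' (changes to stop codons count as non-synonymous), averaged between the
#' two sequences; observed differences `Sd`/`Nd` classify each codon pair
#' over all minimal substitution pathways, excluding pathways through stop
#' codons, with equal weight. Proportions are Jukes-Cantor corrected,
#' `d = -(3/4) log(1 - (4/3) p)`.
#'
#' @param seq_a,seq_b Equal-length in-frame CDS without ambiguity codes.
#' @return List: `N, S` (potential sites), `Nd, Sd` (observed), `pN, pS`,
#'   `dN` (Ka), `dS` (Ks), `ratio` (Ka/Ks, `NA` when `dS == 0`).
#' @export
nei_gojobori <- function(seq_a, seq_b) {
  if (nchar(seq_a) != nchar(seq_b)) stop("sequence length mismatch")
  if (nchar(seq_a) %% 3 != 0) stop("CDS length not divisible by 3")
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (grepl("[^ACGT]", seq_a) || grepl("[^ACGT]", seq_b))
    stop("ambiguity codes not supported")
  ca <- split_codons(seq_a)
  cb <- split_codons(seq_b)
  S <- (sum(codon_syn_sites(ca)) + sum(codon_syn_sites(cb))) / 2
  N <- 3 * length(ca) - S
  Sd <- Nd <- 0
  for (i in seq_along(ca)) {
    if (ca[i] == cb[i]) next
    cnt <- codon_pair_diffs(ca[i], cb[i])
    Sd <- Sd + cnt["syn"]
    Nd <- Nd + cnt["nonsyn"]
  }
  Sd <- unname(Sd); Nd <- unname(Nd)
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  jc <- function(p) {
    if (p >= 3 / 4) stop("proportion >= 3/4: Jukes-Cantor correction undefined")
    -3 / 4 * log(1 - 4 / 3 * p)
  }
  dS <- jc(pS); dN <- jc(pN)
  list(N = N, S = S, Nd = Nd, Sd = Sd, pN = pN, pS = pS, dN = dN, dS = dS,
       ratio = if (dS > 0) dN / dS else NA_real_)
}

# average synonymous/non-synonymous difference counts between two codons
# over all minimal substitution pathways, excluding those through stops
codon_pair_diffs <- function(a, b) {
  pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  if (!length(pos)) return(c(syn = 0, nonsyn = 0))
  perms <- permutations_of(pos)
  syn <- non <- 0; nvalid <- 0
  for (ord in perms) {
    cur <- a
    s <- n <- 0
    ok <- TRUE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(b, p, p)
      if (codon_aa(nxt) == "*") { ok <- FALSE; break }
      if (codon_aa(cur) == codon_aa(nxt)) s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    if (ok) { syn <- syn + s; non <- non + n; nvalid <- nvalid + 1 }
  }
  if (nvalid == 0) {
    # every pathway passes through a stop: count all changes non-synonymous
    return(c(syn = 0, nonsyn = length(pos)))
  }
  c(syn = syn / nvalid, nonsyn = non / nvalid)
}

# all permutations of a small vector (n <= 3 here)
permutations_of <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in permutations_of(x[-i])) out[[length(out) + 1]] <- c(x[i], rest)
  }
  out
}
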