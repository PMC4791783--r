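#' Generate a codon-resolved gene set with target MK counts
#'
#' Builds, per gene, a random in-frame reference CDS and plants exactly the
#' requested numbers of fixed synonymous (`DS`) and non-synonymous (`DN`)
#' differences between the two group consensuses, and synonymous (`PS`) and
#' non-synonymous (`PN`) polymorphisms within groups. Every change occupies
#' its own codon, so recounting the categories from the emitted sequences
#' and variants reproduces the targets exactly; no internal stop codon is
#' ever created.
#'
#' @param n_genes Number of genes.
#' @param codons_per_gene Codons per gene; must be at least
#'   `DS + DN + PS + PN` for every gene (one change per codon).
#' @param targets data.frame with columns `DS, DN, PS, PN`, one row per gene
#'   (recycled if a single row).
#' @param seed Integer seed.
#' @param chrom Chromosome label for gene placement.
#' @param spacer_bp Intergenic gap between consecutive genes.
#' @param strands Strand per gene (recycled), `"+"` or `"-"`.
#' @return Object of class `gene_set`: `genes` (coordinates, 0-based
#'   half-open), `group_sequences` (`control` and `selection` named CDS
#'   vectors, coding strand), `variants` (within-group polymorphisms with
#'   codon index, codon position, alleles, group, syn/nonsyn flag) and
#'   `targets`.
#' @export
gen_mk_gene_set <- function(n_genes, codons_per_gene, targets, seed = 1,
                            chrom = "chrG", spacer_bp = 300L,
                            strands = "+") {
  targets <- as.data.frame(targets)
  stopifnot(all(c("DS", "DN", "PS", "PN") %in% names(targets)))
  if (nrow(targets) == 1 && n_genes > 1)
    targets <- targets[rep(1, n_genes), ]
  stopifnot(nrow(targets) == n_genes)
  if (any(unlist(targets[c("DS", "DN", "PS", "PN")]) < 0))
    stop("targets must be non-negative")
  tot <- rowSums(targets[, c("DS", "DN", "PS", "PN")])
  if (any(tot > codons_per_gene))
    stop("infeasible targets: more changes than available codons")
  strands <- rep_len(strands, n_genes)
  set.seed(derive_seed(seed, 5L))
  code <- codon_code()
  ids <- sprintf("gene%03d", seq_len(n_genes))
  glen <- 3L * codons_per_gene
  starts <- (seq_len(n_genes) - 1L) * (glen + spacer_bp) + spacer_bp
  genes <- data.table(gene_id = ids, chrom = chrom, start = starts,
                      end = starts + glen, strand = strands)
  ctrl <- sel <- setNames(character(n_genes), ids)
  vars <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    tg <- targets[g, ]
    codons <- sample(code$sense, codons_per_gene, replace = TRUE)
    need <- c(rep("DS", tg$DS), rep("DN", tg$DN),
              rep("PS", tg$PS), rep("PN", tg$PN))
    slots <- sample.int(codons_per_gene, length(need))
    sel_codons <- codons
    vrows <- list()
    for (i in seq_along(need)) {
      kind <- need[i]
      idx <- slots[i]
      syn_wanted <- kind %in% c("DS", "PS")
      pick <- pick_codon_change(codons[idx], syn_wanted)
      if (is.null(pick)) {
        # reference codon has no suitable one-step neighbour (e.g. ATG for
        # a synonymous change): replace it by one that does
        codons[idx] <- sample(codons_with_change(syn_wanted), 1)
        sel_codons[idx] <- codons[idx]
        pick <- pick_codon_change(codons[idx], syn_wanted)
      }
      if (kind %in% c("DS", "DN")) {
        sel_codons[idx] <- pick$to
      } else {
        vrows[[length(vrows) + 1L]] <- data.table(
          gene_id = ids[g], codon = idx, codon_pos = pick$pos,
          ref = substr(codons[idx], pick$pos, pick$pos),
          alt = substr(pick$to, pick$pos, pick$pos),
          group = sample(c("control", "selection"), 1),
          effect = if (syn_wanted) "synonymous" else "nonsynonymous")
      }
    }
    ctrl[g] <- paste(codons, collapse = "")
    sel[g] <- paste(sel_codons, collapse = "")
    vars[[g]] <- if (length(vrows)) rbindlist(vrows) else NULL
  }
  variants <- rbindlist(vars[!vapply(vars, is.null, logical(1))])
  if (!nrow(variants))
    variants <- data.table(gene_id = character(), codon = integer(),
                           codon_pos = integer(), ref = character(),
                           alt = character(), group = character(),
                           effect = character())
  structure(list(genes = genes,
                 group_sequences = list(control = ctrl, selection = sel),
                 variants = variants,
                 targets = cbind(gene_id = ids, targets)),
            class = "gene_set")
}

# a random one-step codon change of the requested class avoiding stops;
# NULL if the codon has none
pick_codon_change <- function(codon, synonymous) {
  nb <- codon_neighbors(codon)
  nb <- nb[codon_aa(nb) != "*"]
  ok <- if (synonymous) codon_aa(nb) == codon_aa(codon)
        else codon_aa(nb) != codon_aa(codon)
  nb <- nb[ok]
  if (!length(nb)) return(NULL)
  to <- sample(nb, 1)
  pos <- which(strsplit(codon, "")[[1]] != strsplit(to, "")[[1]])
  list(to = to, pos = pos)
}

# sense codons admitting at least one non-stop change of the given class
codons_with_change <- function(synonymous) {
  code <- codon_code()
  key <- if (synonymous) "has_syn" else "has_nonsyn"
  if (is.null(code[[key]])) {
    ok <- vapply(code$sense, function(cd) {
      nb <- codon_neighbors(cd)
      nb <- nb[codon_aa(nb) != "*"]
      if (synonymous) any(codon_aa(nb) == codon_aa(cd))
      else any(codon_aa(nb) != codon_aa(cd))
    }, logical(1))
    code[[key]] <- code$sense[ok]
  }
  code[[key]]
}

#' @export
print.gene_set <- function(x, ...) {
  cat("gene_set:", nrow(x$genes), "genes,",
      nrow(x$variants), "within-group variants\n")
  invisible(x)
}

#' Recount MK categories from a gene set
#'
#' Inverse of [gen_mk_gene_set()]: recomputes `DS, DN, PS, PN` per gene from
#' the stored consensus sequences and variant list by codon translation.
#'
#' @param gs A `gene_set`.
#' @return data.table with `gene_id, DS, DN, PS, PN`.
#' @export
count_mk_gene_set <- function(gs) {
  out <- lapply(seq_len(nrow(gs$genes)), function(g) {
    id <- gs$genes$gene_id[g]
    v <- gs$variants[gs$variants$gene_id == id, ]
    mk <- mk_counts(gs$group_sequences$control[[id]],
                    gs$group_sequences$selection[[id]],
                    variants = v)
    data.table(gene_id = id, DS = mk$DS, DN = mk$DN,
               PS = mk$PS, PN = mk$PN)
  })
  rbindlist(out)
}

#' Generate a neutrally diverged CDS pair
#'
#' Produces a random in-frame CDS and a copy carrying `n_subs` substitutions
#' at distinct positions, each to a uniformly chosen alternative base
#' (redrawn if it would create an internal stop). Because proposed changes
#' are direction-blind, the true Ka/Ks of the pair is 1 in expectation; used
#' for estimator-calibration tests.
#'
#' @param n_codons Number of codons (>= 2).
#' @param n_subs Number of substitutions.
#' @param seed Integer seed.
#' @return List with `seqA`, `seqB` (character CDS).
#' @export
mutate_cds_neutral <- function(n_codons, n_subs, seed = 1) {
  stopifnot(n_codons >= 2, n_subs <= 3 * n_codons)
  set.seed(derive_seed(seed, 6L))
  code <- codon_code()
  seqA <- paste(sample(code$sense, n_codons, replace = TRUE), collapse = "")
  b <- strsplit(seqA, "")[[1]]
  sites <- sample.int(length(b), n_subs)
  for (s in sites) {
    repeat {
      cand <- sample(setdiff(c("A", "C", "G", "T"), b[s]), 1)
      old <- b[s]
      b[s] <- cand
      ci <- (s - 1L) %/% 3L
      codon <- paste(b[(3 * ci + 1):(3 * ci + 3)], collapse = "")
      if (codon_aa(codon) != "*") break
      b[s] <- old
    }
  }
  list(seqA = seqA, seqB = paste(b, collapse = ""))
}
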