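# ersweep

Genome scans for replicated experimental evolution with pooled sequencing.

`ersweep` is an R toolkit for evolve-and-resequence (E&R) studies in which
replicate populations are driven through tens of generations of directional
selection alongside unselected controls, and each line is then pool-sequenced
(~100 diploid individuals per pool, ~35× coverage). From per-line allele
count tables it reconstructs the full genome-scan battery such experiments
rely on:

- **Variant core** — quality/depth/indel-proximity filtering, the 99 %
  pooled-fixation rule (a site with reference fraction > 99 % or < 1 % is
  called fixed), cross-replicate fixation patterns (one allele fixed in all
  controls, the alternative in all selected lines; single-line discordances),
  per-category SNP density tables and Fisher tests of coding enrichment.
- **Diversity** — sliding-window expected heterozygosity `H = mean 2p(1-p)`,
  nucleotide diversity π, Watterson's θ_W = S/a₁, Tajima's
  `D = (π − θ_W)/√(e₁S + e₂S(S−1))` with the classical constants, and the
  two-pool per-SNP estimator `F_ST = (H_T − H_S)/H_T`.
- **Sweep HMM** — a three-state (Neutral / Intermediate / Selection) hidden
  Markov model over ordered SNPs. Each state emits pooled read counts
  through an allele-frequency spectrum over derived counts `j = 0..n`
  (`ξ(j) ∝ θ/j` for the neutral state; the Selection state concentrates
  mass on the extreme classes), with per-site switch probability
  `k = 10⁻¹⁰`. Forward–backward posteriors (or Viterbi) label sites, and
  runs of Selection sites become sweep regions.
- **Sweep comparison** — base-pair-resolution sharing classification across
  the six lines (line-specific / group-shared / all-shared), shared-length
  ratios between groups, hard-sweep candidate calling (line-specific, mean
  in-region `H ≤ 0.01`, ≥ 100 kb from any shared region), and a positional
  clustering permutation test (mean nearest-neighbour distance against
  resampled draws from the SNP background).
- **Divergence** — group consensus CDS building from fixed genotypes,
  McDonald–Kreitman counts with `DoS = DN/(DN+DS) − PN/(PN+PS)` and exact
  Fisher p-values, and Nei–Gojobori (approximate) Ka/Ks with unweighted
  pathway counting and Jukes–Cantor correction.
- **Forward simulator** — diploid Wright–Fisher resampling with
  recombination over founder haplotypes, supporting the experiment's
  demographic schedule and single-site selection, with windowed
  heterozygosity read-outs and the analytic drift oracle
  `E[H_t] = H₀(1 − 1/2N)^t`.
- **Synthetic data** — founder panels drawn from the neutral spectrum
  `ξ_j ∝ 1/j` over 205 haplotypes, spiked hard/soft sweeps, pooled read
  sampling, and codon-resolved gene sets with exactly prescribed
  DS/DN/PS/PN counts.

## Worked example

```r
library(ersweep)

# McDonald-Kreitman test for a gene with 2 synonymous and 2 non-synonymous
# fixed differences and 22 synonymous polymorphisms:
dos(DS = 2, DN = 2, PS = 22, PN = 0)
#> [1] 0.5
mkt_fisher(2, 2, 22, 0)
#> [1] 0.01846154

# Ka/Ks for a one-codon toy: TTT (Phe) vs TTA (Leu)
str(nei_gojobori("TTT", "TTA")[c("N", "S", "pN", "dN")])
#> List of 4
#>  $ N : num 2.5
#>  $ S : num 0.5
#>  $ pN: num 0.4
#>  $ dN: num 0.572

# End-to-end synthetic run: six lines, one soft sweep shared by the three
# selection lines, one hard sweep private to line S1
gm <- setNames(c(rep("selection", 3), rep("control", 3)),
               c("S1", "S2", "S3", "C1", "C2", "C3"))
res <- run_pipeline(pipeline_config(gm, seed = 5))
res$regions
#>     chrom   line   start     end n_snps mean_posterior
#> 1:   chrS     S1  601862  897721    304      0.9915209
#> 2:   chrS     S1 1803664 2097642    285      0.9905598
#> 3:   chrS     S2  600884  897721    305      0.9932059
#> 4:   chrS     S3  600884  897721    305      0.9929565
```

The HMM finds the spiked soft sweep (~0.6–0.9 Mb) in all three selection
lines — classified `group_shared` — and the hard sweep (~1.8–2.1 Mb) only
in S1, which the candidate rule flags as a hard-sweep signature
(line-specific, near-zero heterozygosity, isolated from shared regions).

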