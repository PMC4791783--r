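---
title: "Models and methods behind ersweep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ersweep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ersweep` analyses evolve-and-resequence (E&R) designs: replicate
populations pushed through directional selection next to unselected
control replicates, each line pool-sequenced at the end. This vignette
describes the statistical models, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate, and
the numerical choices made where the design was genuinely open.

## The experimental design being modelled

The reference design has six lines — three selection, three control — each
pool-sequenced from about 100 diploid females at roughly 35× coverage.
Selection ran for 48 generations at an effective size of about 200
diploids per line, after a founding bottleneck of 120 individuals and a
short mass-culture expansion, and was followed by roughly ten relaxed
generations. `experiment_schedule()` encodes these phases for the forward
simulator.

## Variant processing

Sites enter the pipeline as per-line read counts. A site survives
filtering only if **every** line passes genotype quality (> 30), depth
(10–250) and, when indel positions are supplied, lies more than 10 bp from
any base of an indel's reference span (distance inclusive: a SNP exactly
10 bp away is removed). Multi-allelic sites are dropped. The pooled
fixation call is deliberately strict: with threshold 0.99, a line is fixed
for the alternate allele only when the alternate read fraction strictly
exceeds 0.99, fixed for the reference only when the reference fraction
strictly exceeds 0.99 (computed as `1 - freq > 0.99` so that a fraction of
exactly 0.01 stays polymorphic despite floating-point representation), and
polymorphic otherwise. Cross-replicate patterns are then interval logic:
*experiment-specific* sites have one allele fixed in every control line
and the alternative fixed in every selection line; *single-line
discordant* sites have five lines fixed for one allele and exactly one
line fixed for the other. Sites with any missing call report missing
pattern flags rather than a guess.

Functional annotation resolves overlapping features with the fixed
precedence CDS > 5'-UTR > 3'-UTR > intron > ncRNA > intergenic (a choice
the data cannot make for us); coding sites are classified by translating
the spliced, strand-aware codon before and after substitution. Density
tables report `1000 * count / covered_bp` per category, rounded to two
decimals.

## Diversity statistics

Windowed statistics follow the classical frequency-based forms on pooled
read fractions. Within a window, `S` counts segregating sites, π is
`sum(2 p q) * n/(n-1)`, Watterson's estimator is `S / a1`, and Tajima's D
uses the standard 1989 constants (`a1, a2, b1, b2, c1, c2, e1, e2`). Two
deliberate choices:

- **Heterozygosity averages over all observed sites**, not only
  segregating ones, so that a window whose sites were driven to fixation
  reports `H = 0` rather than missing — exactly the signal a sweep scan
  needs. π, θ and D, by contrast, are undefined below `min_snps`
  segregating sites and report `NA`.
- **Pool-size bias corrections are not applied.** The classical estimators
  are computed on read-derived frequencies with a nominal sample size of
  `n` chromosomes (default 200 = 100 diploids; 100 is equally runnable).
  The corrected estimators of dedicated Pool-seq tools differ by small
  factors that do not change window-to-window contrasts, which is what the
  scan interprets; the classical forms are exactly testable against
  straight-line oracles.

Between pools `i` and `j`, per-SNP differentiation is
`F_ST = (H_T - H_S)/H_T` with `H_S` the mean of the two pool
heterozygosities and `H_T` from the mean frequency; sites monomorphic in
both pools are skipped. Pair means average over SNPs first, then over
pairs.

## The sweep HMM

Sweep detection uses a three-state HMM over position-ordered SNPs:
Neutral, Intermediate, Selection. Each state emits the observed alternate
read count through a binomial mixture over derived-allele classes
`j = 0..n`:

```
log P(alt | depth, state) = log sum_j xi_state(j) * Binom(alt; depth, j/n)
```

The Neutral spectrum gives polymorphic classes mass `theta / j`
(`j = 1..n-1`), with the remaining mass on the monomorphic classes split
by an ancestral-allele prior (default 0.5). The Selection spectrum is a
mixture `(1 - p_e) * (extreme point mass) + p_e * Neutral` with escape
weight `p_e = 0.05`; the Intermediate state uses `p_e = 0.5`. This
mixture form preserves the essential contrast — selection shifts mass to
extreme frequencies — without claiming to reproduce any trained spectrum.
Transitions are symmetric with off-diagonal `k = 1e-10` (the very sticky
prior appropriate when single-site evidence is weak but sweeps span
hundreds of SNPs), so the stationary initial distribution is uniform.
Decoding is forward–backward in log space with per-site argmax (Viterbi is
available); maximal runs of Selection sites become regions
`[first SNP, last SNP + 1)`.

`theta` defaults to the Watterson estimate `S / (a1 * covered_sites)`
where *covered sites* are the rows of the input table. For pileup-style
input (every covered position a row) this is the per-bp estimate; for a
SNP-only table it conditions the spectrum on the ascertained sites, which
is what makes the Neutral and Selection states distinguishable at all when
monomorphic positions are not in the data — with a per-bp estimate on a
SNP table the Neutral spectrum would be ~99.9 % monomorphic and fixed
sites would carry virtually no evidence either way. Users with sparse
tables and a known covered length can pass `covered_bp` or set `theta`
directly.

## Cross-replicate comparison

Sharing is computed at base-pair resolution by interval algebra: a base is
*all-shared* when covered by sweep regions of all six lines, *group-shared*
(for a line) when covered by every line of that line's group, and
*line-specific* when covered by exactly one line; each line's regions are
partitioned into disjoint classified segments so lengths are conserved.
Hard-sweep candidates are line-specific regions with mean in-region
heterozygosity at most 0.01 that lie at least 100 kb (one heterozygosity
window — the data give no sharper notion of "adjacent") from any shared
region. The in-region mean uses windows fully contained in the region when
any exist; boundary-straddling windows mix in flanking diversity and serve
only as a fallback for regions shorter than one window.

The positional clustering test uses mean nearest-neighbour distance among
the focal positions as its statistic — chosen as the simplest scale-free
measure of 1-D clustering, since no canonical statistic exists for this
design — against a null of `R` draws of equally many positions from the
background without replacement, with the add-one estimator
`p = (1 + #(null <= observed)) / (R + 1)`. With the default `R = 1e5` the
smallest attainable p is 1e-5.

## Divergence tests

Group consensus CDS are the reference with group-fixed alternate alleles
substituted, strand-aware. MK counts classify each differing nucleotide by
toggling it alone in its codon context; polymorphisms (pooled across both
groups, as the test's within-population margin does not resolve groups)
take precedence over divergence at the same position, avoiding double
counting. `DoS = DN/(DN+DS) - PN/(PN+PS)` is reported only when both
denominators are positive; the Fisher p-value is the exact two-sided
summation of hypergeometric point probabilities (implemented with
vectorised `dhyper`, so genome-scale tables with margins near a million are
exact and fast; verified against `stats::fisher.test`). Tables with a zero
margin are uninformative and report `p = 1` with a flag.

Ka/Ks follows the approximate pathway-counting method: potential
synonymous sites per codon are the per-position fractions of one-step
changes that preserve the amino acid (changes creating stops count as
non-synonymous opportunities), averaged between the two sequences;
observed differences average over all minimal substitution pathways with
pathways through stop codons excluded (if every pathway passes through a
stop, all changes count as non-synonymous). Proportions are Jukes–Cantor
corrected, `d = -(3/4) log(1 - (4/3) p)`, undefined at `p >= 3/4`.

## Forward simulation

The simulator is diploid Wright–Fisher with fecundity selection: each
offspring draws a parent with probability proportional to genotype fitness
(uniform when neutral) per gamete, and each gamete recombines the parent's
two haplotypes with a Poisson number of crossovers placed uniformly.
Selection acts on a single site with genotype fitness `(w0, w1, w2)`;
the default heterozygote is the additive midpoint, and in the reference
scenario `(0.2, 2.1, 4.0)` — baseline homozygote 0.2, beneficial
homozygote 4.

**Recombination units.** The rate can be given as cM/Mb or as expected
crossovers per chromosome per meiosis (the convention of chromosome-level
forward simulators). The distinction matters: with the experiment's
parameters, a density of 0.02 crossovers/Mb (2 cM/Mb) leaves a
depleted-heterozygosity footprint around a fixed selected allele of about
6 Mb, whereas 2 crossovers per ~23 Mb chromosome arm (~0.087/Mb) gives
about 2 Mb — the footprint scale that matches the reference experiments'
simulations. The experiment-mimicking scenario (`sweep_span_experiment()`)
therefore uses the per-chromosome convention scaled to that density;
both unit modes are exposed in `sim_config()`.

**Scaling.** The 1000-generation mass-breeding phase at N = 100,000 is a
desk-scale impossibility and, for founder panels without linkage
disequilibrium, nearly a no-op (per-generation heterozygosity loss
1/2N = 5e-6). The desk preset rescales it to 100 generations at N = 1000;
the full values remain available for cluster use. Test-suite and
acceptance runs use chromosomes of 2–10 Mb with 1,000–10,000 founder
sites — large enough to hold a multi-Mb sweep footprint, small enough for
minutes-scale runs on one CPU.

The analytic oracle `E[H_t] = H0 (1 - 1/(2N))^t` validates neutral runs
(one extra factor accounts for the binomial founding draw of the 2N
simulated haplotypes). Under neutrality the selected-site frequency is a
martingale; both properties are tested.

## The synthetic-data generator

Founder panels draw derived-allele counts from the neutral spectrum
`P(j) ∝ 1/j` over 205 haplotypes (the scale of a community inbred-line
panel), at uniform positions, with independent sites by default — there is
no empirical linkage disequilibrium model to copy, and the HMM consumes
frequencies, not haplotypes; an optional block-mosaic mode provides LD for
stress tests. Pool sampling is Poisson depth with binomial alternate reads
(error `e` enters as `p(1-e) + (1-p)e`; default 0, as base-level filtering
happens upstream of this package). Spiked sweeps overwrite in-region
frequencies with one standing haplotype's alleles — the same haplotype
across replicates for a soft sweep, one replicate only for a hard sweep.
The MK gene-set generator plants each targeted change in its own codon, so
recounting is exactly the identity; that makes it an oracle for the
divergence module but also means it does not emulate multi-hit codons,
codon usage bias or realistic gene structure. Passing tests on these
fixtures therefore demonstrates correctness of the counting and detection
machinery, not calibration against real Pool-seq noise (alignment
artefacts, depth heterogeneity beyond Poisson, reference bias).

## Degenerate inputs and tie-breaks

Empty windows report missing statistics; HMM posteriors are renormalised
against accumulated rounding and asserted to sum to one within 1e-9;
posterior ties resolve to the first state in (neutral, intermediate,
selection) order; Fisher tail sums use a `1 + 1e-7` relative guard so
equal-probability tables are counted despite floating-point noise; the
permutation p-value uses the add-one estimator and so is never zero.
Seeds: every generator and simulation is a pure function of its arguments
including an integer seed; internal child seeds are derived
deterministically and kept below 2^31.

## Known limitations

- Classical (uncorrected) diversity estimators on read frequencies; no
  pool-size correction.
- The HMM's state spectra are the mixture forms above, not spectra trained
  from data; region counts on real data will differ from tools trained
  otherwise.
- The simulator is autosomal-only (no X dosage), with fitness acting on
  parental sampling; selfing-free random mating.
- The clustering permutation statistic is one reasonable choice among
  several; inference should not hinge on its exact p.
- GO enrichment and read mapping/genotyping live outside this package: the
  pipeline starts at variant tables.
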