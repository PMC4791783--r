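Package: ersweep
Title: Genome Scans for Replicated Experimental Evolution with Pooled Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for evolve-and-resequence (E&R) experiments with
    pooled sequencing of replicate lines. Provides variant filtering and
    fixation-pattern scanning across selection and control replicates,
    sliding-window diversity statistics (expected heterozygosity, nucleotide
    diversity, Watterson's theta, Tajima's D, per-SNP FST), a three-state
    hidden Markov model over the pooled allele-frequency spectrum for
    selective-sweep detection, cross-replicate sweep sharing classification
    with hard-sweep candidate calling and a positional clustering permutation
    test, McDonald-Kreitman tests with the DoS statistic and Nei-Gojobori
    Ka/Ks estimation, a Wright-Fisher forward simulator with recombination
    over founder haplotypes, and a synthetic Pool-seq data generator that
    emulates the full experimental design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    methods,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
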