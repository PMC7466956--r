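Package: mutacc
Title: Mutation-Accumulation Experiment Analysis for AT-Rich, Repeat-Dense Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of haploid mutation-accumulation (MA)
    experiments: per-line and pooled base-substitution and indel mutation
    rates with BCa bootstrap confidence intervals, the six-class
    strand-symmetric substitution spectrum with conditional rates,
    mutation-equilibrium GC content and GC/AT bias, multinucleotide-mutation
    (MNM) clustering with a Poisson goodness-of-fit correction, simple
    sequence repeat (SSR) detection and slippage-indel context annotation,
    neutral nonsynonymous/synonymous expectations from codon usage, indel
    size accounting, and effective population size from nucleotide
    diversity. Includes a forward simulator of an MA experiment over an
    AT-rich, SSR-dense genome so that every estimator is testable by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    boot,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
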