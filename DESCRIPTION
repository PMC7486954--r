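Package: mutacc
Title: Mutation Accumulation Experiment Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of mutation accumulation (MA) experiments in
    unicellular organisms, from filtered de novo mutation calls to per-site
    and per-genome mutation rates with exact Poisson confidence intervals.
    Implements the callable-site definition and acceptance criteria used to
    call de novo single-nucleotide mutations from resequenced MA lines, a
    minimal functional-effect classifier, mutation-spectrum and
    equilibrium-GC analysis, codon-usage-bias estimation of the strength of
    selection (effective number of codons, frequency of optimal codons,
    Sharp's S under mutation-selection-drift equilibrium), and effective
    population size and molecular-clock syntheses. A synthetic MA-experiment
    generator reproduces the statistical structure of a serial-bottleneck
    experiment (diploid genome, Poisson mutation counts, configurable
    spectrum, variant-call artifacts, codon usage, growth trajectories) so
    the whole pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
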