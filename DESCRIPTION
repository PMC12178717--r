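Package: popcoal
Title: Coalescent Demographic Inference and Admixture Tests from Diploid
    Consensus Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring historical effective population size and
    divergence from whole-genome diploid consensus sequences encoded with
    IUPAC ambiguity codes. Implements a pairwise sequentially Markovian
    coalescent (PSMC-style) hidden Markov model fitted by
    expectation-maximization, pseudo-diploid construction for
    divergence-time read-off, genome-wide heterozygosity summaries with
    repeat-mask handling, neighbor-joining distance trees with
    Jukes-Cantor or Poisson correction, and ABBA-BABA D-statistics with
    block-jackknife standard errors. A sequentially Markovian coalescent
    genome simulator with piecewise-constant population sizes, clean
    population splits and admixture pulses provides fully reproducible
    synthetic data for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    IRanges,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
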