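Package: chronosim
Title: Simulation and Evaluation of Phylogenies with Co-Evolving
    Speciation and Substitution Rates
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Forward-time birth-death simulation of phylogenies in which
    lineage-specific speciation rates and molecular substitution rates
    evolve jointly by (correlated) Brownian motion, with optional
    punctuated bursts of substitutions at speciation events.  Trees are
    conditioned on a fixed number of extant tips with the Generalised
    Sampling Approach.  The package simulates nucleotide alignments
    along the resulting phylograms, emits node-age calibrations and
    input bundles for external Bayesian dating software, and provides
    the evaluation toolkit used to benchmark molecular dating methods:
    median absolute percentage error of node ages, Robinson-Foulds and
    branch-score distances, highest-posterior-density interval widths,
    the gamma statistic, and sister-pair contrast regressions of clade
    size against median branch length.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    phangorn,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
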