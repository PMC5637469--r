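Package: delselect
Title: Simulation and Sequencing Readout of DNA-Encoded Library Mock Selections
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for modelling one round of in vitro selection of a
    DNA-encoded small-molecule library with a diluted positive-control
    spike-in. Provides a two-class Bernoulli survival model of
    biotin-streptavidin capture with closed-form expected enrichment,
    multinomial sampling at finite sequencing depth, an Illumina-like
    paired-end read simulator with substitution errors and adapter
    read-through, quality-aware overlap merging of read pairs,
    primer-anchored barcode extraction, per-barcode fold-enrichment
    analysis with pseudocounts and confidence intervals, and an
    in-silico restriction-digest readout emulating gel-based monitoring
    of a spike-in carrying an EcoRV site.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
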