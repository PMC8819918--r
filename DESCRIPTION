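Package: ampliBias
Title: Comparing Targeted qPCR Quantification with 16S rRNA Amplicon
    Sequencing of Microbial Communities
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for the quantitative comparison of high-throughput qPCR
    (absolute abundances, copies per microlitre) and 16S rRNA gene amplicon
    sequencing (relative read counts) measurements of the same microbial
    communities. Implements standard-curve based qPCR quantification with
    detection-limit censoring and triplicate rules, gene copy-number and
    taxon-group corrections for amplicon counts, detection-category
    classification, coverage statistics, Bray-Curtis dissimilarity with UPGMA
    clustering of paired method profiles, and estimation of per-taxon
    compositional measurement bias with bootstrap geometric standard errors.
    Includes a synthetic cheese-community simulator with known ground truth
    for validating the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ape
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AbundanceTable-methods.R'
    'bias.R'
    'compare.R'
    'io.R'
    'ngs.R'
    'qpcr.R'
    'report.R'
    'synthetic.R'
    'utils.R'
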