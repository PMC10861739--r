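Package: modpanel
Title: Targeted Blood Transcript Panel Design from Module Repertoire Fingerprints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing targeted whole-blood transcript panels from
    longitudinal transcriptome cohorts analysed against a fixed transcriptional
    module repertoire. Computes module-level percent-response fingerprints
    versus a postpartum baseline, selects responsive module aggregates,
    delineates cross-cohort-consistent module sets by co-clustering of
    response trajectories, and runs a staggered three-step gene screen
    (abundance, correlation with the module-set mean, literature relevance)
    to assemble a fixed-size panel of test and housekeeping genes. Includes
    a synthetic-data generator that emulates paired sequencing- and
    array-based pregnancy cohorts with planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    fgsea,
    ggplot2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'delineation.R'
    'design.R'
    'fingerprint.R'
    'modpanel-package.R'
    'panel.R'
    'repertoire-io.R'
    'selection.R'
    'simulate.R'
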