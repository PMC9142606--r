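Package: lipokineScreen
Title: Lipid Co-Regulation Networks and Stress-Effector Screens for
    Targeted Lipidomics and Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantification and screening pipeline for nominating
    stress-limiting lipokines and their protein effectors from targeted
    lipidomics and label-free proteomics. Parses lipid shorthand
    nomenclature, normalises species intensities to per-subclass relative
    proportions and percent-of-vehicle time courses, infers thresholded
    Pearson co-regulation networks over mean condition profiles, screens
    species for anti-correlation with an external stress readout, runs
    differential screens with the two-stage adaptive linear step-up
    (Benjamini-Krieger-Yekutieli) false discovery rate procedure, and
    filters proteomes for concordantly regulated, lipid-rescued effector
    candidates. Includes seeded synthetic-data generators with planted
    signal so the whole chain is testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3), SummarizedExperiment
Imports: methods, stats, utils, tools, S4Vectors, igraph, jsonlite, yaml
Suggests: testthat (>= 3.0.0), xml2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'diff-screen.R'
    'effectors.R'
    'io.R'
    'lipid-model.R'
    'network.R'
    'pipeline.R'
    'quantify.R'
    'simulate.R'
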