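Package: mirvar
Title: Thermodynamic and Structural Effects of Genetic Variants on
    miRNA Binding Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores the effect of genetic variants located within or near
    microRNA binding sites on miRNA:target interactions. Implements an
    intermolecular nearest-neighbor duplex model (hybrid free energy), an
    exact Boltzmann-ensemble partition function with per-nucleotide
    single-strandedness and constrained opening energies (total
    hybridization energy and block accessibilities), canonical seed-site
    classification, and cohort-level variant density, conservation and
    allele-frequency statistics. Ships a seeded synthetic-cohort generator
    emulating CLASH-style chimeric interaction data with known ground
    truth for every downstream stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'formats-io.R'
    'energy-model.R'
    'rna-energy.R'
    'site-features.R'
    'variant-effects.R'
    'cohort-stats.R'
    'mirvar-package.R'
    'synthetic-data.R'
    'pipeline.R'
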