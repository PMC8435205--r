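Package: moonjelly
Title: Morphometric Dissimilarity and Molecular Species Diagnosis for Moon
    Jellyfish
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for integrative taxonomy of the moon-jellyfish
    genus Aurelia. One arm performs allometric size correction of medusa
    morphometric traits (Lleonart standardization), locality-aware imputation
    of missing measurements, feature filtering, Gower dissimilarity, non-metric
    multidimensional scaling with weighted-average feature scores, and a Mantel
    permutation test against geographic distance. The other arm performs
    phylogeny-based species delimitation: monophyly and node-support screening
    of species hypotheses, identification and categorization of diagnostic
    molecular synapomorphies from most-parsimonious reconstructions (unique /
    non-unique, homoplastic / non-homoplastic, ambiguous), uncorrected
    p-distance summaries with barcode-gap assessment, and sequence-set
    completeness and chimerism bookkeeping. Synthetic-data generators with
    known ground truth make every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    vegan,
    geosphere,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    cluster
Config/testthat/edition: 3
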