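Package: venomdiv
Title: Diet Diversity and the Diversity of Snake Venom Composition
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Comparative analysis of snake diet breadth and venom-toxin
    diversity. Computes Shannon and Gini-Simpson diversity indices on
    compositional venomics and diet-record tables, selects a maximum clade
    credibility tree from a dated posterior sample, and fits a bivariate
    Brownian-motion phylogenetic regression that incorporates intraspecific
    (among-record) variation, with likelihood-ratio inference and a
    multi-restart fitting protocol. Includes a synthetic-data generator
    producing trees, correlated diversity traits, and Dirichlet/multinomial
    compositional records with known ground truth, so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
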