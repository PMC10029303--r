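Package: plastevo
Title: Gene Expression Plasticity and Its Evolution in Reciprocal
    Transplant Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for gene expression plasticity and its
    evolution in reciprocal transplant experiments with ancestral and
    derived populations acclimated to two common gardens. Implements
    selection of adaptation-associated genes by pi and delta-pi
    statistics, decomposition of expression change into plastic (PC),
    genetic (GC), back-garden genetic (GC_b) and total (TC) components,
    classification of reinforcing versus reversing plasticity with a
    parametric bootstrap null, classification of plasticity persistence
    versus evolution from the GC_b-to-GC ratio, signed weighted
    co-expression networks with topological overlap and intramodular
    connectivity, and a synthetic count-data generator with known
    ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
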