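Package: tipin
Title: Protein Complex Identification from Temporal Interval Protein
    Interaction Networks
Version: 0.1.0
Authors@R:
    person("The tipin authors", role = c("aut", "cre"),
           email = "tipin-maintainers@example.org")
Description: Constructs dynamic temporal-interval protein-protein
    interaction networks (TI-PINs) from a scored static interaction
    network and time-course gene expression, identifies protein
    complexes by seed expansion under joint-colocalization,
    joint-coexpression and Gene Ontology similarity conditions, and
    scores predicted complexes against a reference catalog with a full
    suite of matching metrics and hypergeometric enrichment analysis.
    Includes a synthetic-data generator with planted ground-truth
    complexes so the entire pipeline can be exercised without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
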