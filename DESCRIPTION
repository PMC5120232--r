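Package: maxrelnet
Title: Network-Neighborhood Enrichment Features and Max-Relevance
    Ranking for Disease Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Encodes genes as -log10 upper-tail hypergeometric enrichment
    scores between their protein-protein interaction neighborhoods and
    GO-term / KEGG-pathway gene sets, ranks the resulting features by
    mutual information against a binary disease label (the Max-Relevance
    criterion of mRMR), and selects features above an MI threshold with
    per-category reporting. Includes readers for gene lists, STRING-style
    edge lists and GMT gene-set files, a planted-signal synthetic study
    generator for benchmarking recovery, and an end-to-end pipeline driver
    with a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    graphics,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
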