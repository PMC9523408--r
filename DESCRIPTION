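Package: simlink
Title: Cross-Disease Functional Similarity from Replicated Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the functional link between two diseases from
    replicated case/control expression datasets. Calls differentially
    expressed genes per dataset by fold change and Mann-Whitney test and
    intersects them per disease; scores Gene Ontology semantic similarity
    between the two disease gene sets with five measures (Wang, Resnik,
    Lin, Jiang, Rel) and a Monte-Carlo permutation null; tests cross-set
    connectivity in a score-thresholded protein-interaction network with
    the same permutation scheme; ranks hub genes by degree; and performs
    hypergeometric term enrichment with Benjamini-Hochberg correction.
    Includes a synthetic-data generator with planted ground truth so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
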