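Package: netclosure
Title: Literature-Based Discovery of Biological Interaction Networks by
    Vector-Space Retrieval and Transitive Closure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds networks of biological entity interactions (disease,
    drug, gene, target) from a dated textual collection using the vector
    space model: entity occurrences are detected by dictionary phrase
    matching over synonym clusters, weighted by TFIDF, and scored by
    cosine similarity against entity-conjunction queries.  Known
    interactions seed a category-constrained transitive-closure
    inference that predicts and ranks new interactions with an
    iteration penalty, and a year-sliced hold-out protocol checks which
    predictions are later confirmed by newly issued documents.  Includes
    a seeded synthetic-corpus generator with planted co-occurrence and
    closure structure for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr (>= 1.1.0),
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stringr,
    tibble,
    tidyr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
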