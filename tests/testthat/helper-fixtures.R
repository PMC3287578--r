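# In-code fixtures shared across the suite.

# quick lexicon builder: make_lexicon(drug = c("m1", "m2"), disease = "d1")
make_lexicon <- function(...) {
  cats <- list(...)
  rows <- lapply(names(cats), function(ct) {
    tibble::tibble(representative = cats[[ct]], category = ct,
                   synonyms = rep(list(character()), length(cats[[ct]])))
  })
  lexicon(dplyr::bind_rows(rows))
}

# corpus from texts; ids A, B, C, ... and dates spread over one year
make_corpus <- function(texts, year = 2000) {
  n <- length(texts)
  corpus(tibble::tibble(
    id = sprintf("D%02d", seq_len(n)),
    date = as.Date(sprintf("%d-01-01", year)) + seq_len(n) - 1,
    text = texts
  ))
}

# lexicon with generic cluster names for abstract closure matrices:
# categories ca, cb (, cc) with clusters a1.., b1.., c1..
matrix_lexicon <- function(n_a, n_b, n_c = NULL) {
  cats <- list(ca = sprintf("a%d", seq_len(n_a)),
               cb = sprintf("b%d", seq_len(n_b)))
  if (!is.null(n_c)) cats$cc <- sprintf("c%d", seq_len(n_c))
  do.call(make_lexicon, cats)
}

# known-cell table for network_from_interactions from a compact spec:
# known_cells("caxcb", "a1|b1" = 0.9, "a1|b2" = 0.8)
known_cells <- function(subnetwork, ...) {
  lv <- c(...)
  tibble::tibble(subnetwork = subnetwork, entities = names(lv),
                 level = unname(lv))
}

# the 3x3 chain fixture: five knowns on a bipartite path, two inference
# iterations to fixpoint (expected values hand-computed)
chain_fixture <- function() {
  lex <- matrix_lexicon(3, 3)
  known <- known_cells(
    "caxcb",
    "a1|b1" = 0.9, "a2|b1" = 0.8, "a2|b2" = 0.7,
    "a3|b2" = 0.6, "a3|b3" = 0.5
  )
  list(
    lexicon = lex,
    known = known,
    expected_new = tibble::tibble(
      entities = c("a1|b2", "a1|b3", "a2|b3", "a3|b1"),
      iteration = c(1L, 2L, 1L, 1L),
      level = c(0.8, (0.8 + 0.6 + 0.9) / 3 / 2, 0.6, 0.7)
    )
  )
}

# temporal fixture: one closure pattern in 2003, confirmed in 2004
temporal_sim <- function(seed = 7) {
  generate_corpus(simulation_config(
    categories = c(disease = 3, drug = 3),
    n_documents = 12,
    year_range = c(2003, 2003),
    planted_closures = list(list(x = "disease01", z = "disease02",
                                 y = "drug01", w = "drug02",
                                 confirm_year = 2004)),
    seed = seed
  ))
}

expect_tibble_equal <- function(actual, expected, tol = 1e-9) {
  expect_equal(as.data.frame(actual), as.data.frame(expected),
               tolerance = tol, ignore_attr = TRUE)
}

# frequency lookup helper for occurrence-index assertions
occurrence_count_of <- function(idx, doc_id, entity) {
  hit <- idx$counts$f[idx$counts$doc_id == doc_id & idx$counts$entity == entity]
  if (length(hit) == 0) 0L else hit[[1]]
}

# entity_weights object with explicit weights (for similarity properties)
manual_weights <- function(doc_weights) {
  weights <- purrr::imap(doc_weights, function(w, id) {
    tibble::tibble(doc_id = id, entity = names(w), weight = unname(w))
  }) |>
    purrr::list_rbind() |>
    dplyr::filter(weight != 0)
  norms <- purrr::imap(doc_weights, function(w, id) {
    tibble::tibble(doc_id = id, norm = sqrt(sum(w^2)))
  }) |>
    purrr::list_rbind()
  structure(
    list(weights = weights, norms = norms,
         idf = tibble::tibble(entity = character(), idf = double()),
         idf_base = exp(1), n_docs = length(doc_weights)),
    class = "entity_weights"
  )
}
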