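test_that("tf, idf and the weight product follow the TFIDF definitions", {
  expect_equal(term_frequency(3, 3), 1.0)
  expect_equal(term_frequency(0, 5), 0.0)
  expect_equal(term_frequency(1, 4), 0.25)
  expect_equal(term_frequency(0, 0), 0.0)
  expect_error(term_frequency(6, 5), class = "netclosure_tf_inconsistency")

  expect_equal(inverse_document_frequency(4, 4), 0.0)
  expect_equal(inverse_document_frequency(4, 2), log(2), tolerance = 1e-9)
  expect_equal(inverse_document_frequency(1000, 1), log(1000), tolerance = 1e-9)
  expect_equal(inverse_document_frequency(8, 2, base = 2), 2)
  expect_error(inverse_document_frequency(4, 0),
               class = "netclosure_idf_undefined_entity")
  expect_error(inverse_document_frequency(4, 5),
               class = "netclosure_idf_inconsistency")

  expect_equal(entity_weight(1.0, 0.6931), 0.6931)
  expect_equal(entity_weight(0, 3.2), 0)
  expect_equal(entity_weight(0.7, 0), 0)
})

test_that("the weight matrix equals entrywise scalar evaluation", {
  lex <- make_lexicon(drug = c("m1", "m2"), disease = c("d1", "d2"))
  docs <- make_corpus(c(
    "m1 m1 d1",        # f(m1)=2, f(d1)=1, max=2
    "m1 d2 d2 d2",     # f(m1)=1, f(d2)=3, max=3
    "m2 d1",           # f=1 each, max=1
    "m2 m2 m2 m2"      # f(m2)=4, max=4
  ))
  idx <- count_occurrences(docs, lex)
  W <- build_weight_matrix(idx)

  # independent scalar-by-scalar evaluation from hand-tallied counts
  N <- 4
  n_of <- c(m1 = 2, m2 = 2, d1 = 2, d2 = 1)
  f <- list(D01 = c(m1 = 2, d1 = 1), D02 = c(m1 = 1, d2 = 3),
            D03 = c(m2 = 1, d1 = 1), D04 = c(m2 = 4))
  for (doc in names(f)) {
    max_f <- max(f[[doc]])
    for (ent in names(f[[doc]])) {
      expected <- (f[[doc]][[ent]] / max_f) * log(N / n_of[[ent]])
      got <- W$weights$weight[W$weights$doc_id == doc &
                                W$weights$entity == ent]
      expect_equal(got, expected, tolerance = 1e-9,
                   info = paste(doc, ent))
    }
  }
  # norms cover all t entities of the document
  for (doc in names(f)) {
    max_f <- max(f[[doc]])
    expected_norm <- sqrt(sum(
      ((f[[doc]] / max_f) * log(N / n_of[names(f[[doc]])]))^2
    ))
    expect_equal(W$norms$norm[W$norms$doc_id == doc], expected_norm,
                 tolerance = 1e-9)
  }

  # a single-document collection forces idf = 0 everywhere
  idx1 <- count_occurrences(make_corpus("m1 d1"), lex)
  W1 <- build_weight_matrix(idx1)
  expect_equal(nrow(W1$weights), 2)
  expect_true(all(W1$weights$weight == 0))
})

test_that("conjunction queries keep only documents with every entity", {
  lex <- make_lexicon(drug = c("m1", "m2"), disease = c("d1", "d2"),
                      gene = "g1")
  docs <- make_corpus(c("m1 d1", "m1", "d1", "m1 d1 g1"))
  idx <- count_occurrences(docs, lex)
  expect_equal(matching_documents(c("m1", "d1"), idx), c("D01", "D04"))
  expect_equal(matching_documents(c("m2", "d2"), idx), character(0))
  expect_equal(matching_documents(c("m1", "d1", "g1"), idx), "D04")
  expect_error(matching_documents(c("m1", "unknown entity"), idx),
               class = "netclosure_unknown_entity")
})

test_that("cosine similarity matches hand evaluation and stays in [0,1]", {
  # document with weights (0.5, 0.5, 0.5) over three entities, query on two:
  # sim = (0.5+0.5) / (sqrt(0.75) * sqrt(2)) = 0.8165
  W <- manual_weights(list(DOC = c(e1 = 0.5, e2 = 0.5, e3 = 0.5)))
  expect_equal(similarity(c("e1", "e2"), "DOC", W),
               1.0 / (0.8660254 * 1.4142136), tolerance = 1e-6)

  # collinear: only the query entities, equal weights -> exactly 1
  W2 <- manual_weights(list(DOC = c(e1 = 0.3, e2 = 0.3)))
  expect_equal(similarity(c("e1", "e2"), "DOC", W2), 1.0, tolerance = 1e-12)

  # degenerate zero norm scores 0 with a warning
  W0 <- manual_weights(list(DOC = c(e1 = 0, e2 = 0)))
  expect_warning(s <- similarity(c("e1", "e2"), "DOC", W0),
                 class = "netclosure_zero_norm")
  expect_equal(s, 0)
})

test_that("similarity is scale invariant and decreases with off-query mass", {
  set.seed(21)
  for (i in 1:20) {
    w <- runif(4, 0.1, 2)
    names(w) <- c("e1", "e2", "e3", "e4")
    q <- c("e1", "e2")
    s1 <- similarity(q, "DOC", manual_weights(list(DOC = w)))
    expect_gte(s1, 0)
    expect_lte(s1, 1 + 1e-12)
    # positive rescaling of the document leaves the cosine unchanged
    s2 <- similarity(q, "DOC", manual_weights(list(DOC = w * 7.3)))
    expect_equal(s1, s2, tolerance = 1e-9)
    # adding weight on a non-query entity strictly lowers the similarity
    w_more <- w
    w_more["e3"] <- w["e3"] + 0.5
    s3 <- similarity(q, "DOC", manual_weights(list(DOC = w_more)))
    expect_lt(s3, s1)
  }
})

test_that("the idf base rescales weights but leaves similarities unchanged", {
  lex <- make_lexicon(drug = c("m1", "m2"), disease = c("d1", "d2"))
  docs <- make_corpus(c("m1 d1 d1", "m1 d2", "m2 d1 filler", "m2 m1"))
  idx <- count_occurrences(docs, lex)
  We <- build_weight_matrix(idx, idf_base = exp(1))
  W2 <- build_weight_matrix(idx, idf_base = 2)
  expect_equal(W2$weights$weight, We$weights$weight / log(2),
               tolerance = 1e-12)
  r_e <- query_similarities(c("m1", "d1"), We, idx)
  r_2 <- query_similarities(c("m1", "d1"), W2, idx)
  expect_equal(r_e, r_2, tolerance = 1e-12)
})

test_that("query similarities are sorted and match per-document recomputation", {
  lex <- make_lexicon(drug = c("m1", "m2"), disease = c("d1", "d2"))
  docs <- make_corpus(c("m1 d1", "m1 m1 d1 d2", "m1 d1 d1 m2", "m2 d2"))
  idx <- count_occurrences(docs, lex)
  W <- build_weight_matrix(idx)
  res <- query_similarities(c("m1", "d1"), W, idx)
  expect_equal(sort(res$doc_id), c("D01", "D02", "D03"))
  expect_true(all(diff(res$similarity) <= 1e-12))
  for (i in seq_len(nrow(res))) {
    expect_equal(res$similarity[i], similarity(c("m1", "d1"), res$doc_id[i], W),
                 tolerance = 1e-9)
  }
  expect_equal(nrow(query_similarities(c("m2", "d1"), W, idx)), 1)
  empty <- query_similarities(c("m2", "d2"), W, idx)
  expect_equal(empty$doc_id, "D04")
})

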