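test_that("closure triples are found on the textbook 2x2 pattern", {
  lex <- matrix_lexicon(2, 2)
  net <- network_from_interactions(lex, known_cells(
    "caxcb", "a1|b1" = 0.6, "a1|b2" = 0.9, "a2|b1" = 0.3
  ))
  tri <- find_closure_triples(net, "caxcb", "a2|b2")
  expect_equal(nrow(tri), 1)
  expect_setequal(c(tri$cell_xy, tri$cell_xw, tri$cell_zy),
                  c("a1|b1", "a1|b2", "a2|b1"))
  expect_equal(tri$candidate, (0.6 + 0.9 + 0.3) / 3, tolerance = 1e-12)

  # two known cells cannot support any triple
  net2 <- network_from_interactions(lex, known_cells(
    "caxcb", "a1|b1" = 0.6, "a1|b2" = 0.9
  ))
  expect_equal(nrow(find_closure_triples(net2, "caxcb", "a2|b2")), 0)
  expect_error(find_closure_triples(net, "caxcb", "a1|b1"))  # not absent
})

test_that("triple sets equal exhaustive quadruple enumeration on random matrices", {
  set.seed(41)
  for (rep_i in 1:15) {
    n_a <- sample(3:5, 1)
    n_b <- sample(3:5, 1)
    lex <- matrix_lexicon(n_a, n_b)
    known <- random_known(list(ca = sprintf("a%d", 1:n_a),
                               cb = sprintf("b%d", 1:n_b)), density = 0.45)
    if (nrow(known) < 3) next
    net <- network_from_interactions(lex, dplyr::mutate(known, subnetwork = "caxcb"))
    lv <- stats::setNames(known$level, known$entities)
    absent <- setdiff(
      as.vector(outer(sprintf("a%d", 1:n_a), sprintf("b%d", 1:n_b),
                      paste, sep = "|")),
      known$entities
    )
    for (target in absent) {
      tri <- find_closure_triples(net, "caxcb", target)
      # oracle: all (x, y) quadruple combinations around the target
      parts <- strsplit(target, "|", fixed = TRUE)[[1]]
      z <- parts[1]; w <- parts[2]
      expected <- list()
      for (x in setdiff(sprintf("a%d", 1:n_a), z)) {
        for (y in setdiff(sprintf("b%d", 1:n_b), w)) {
          cells <- c(paste(x, y, sep = "|"), paste(x, w, sep = "|"),
                     paste(z, y, sep = "|"))
          if (all(cells %in% known$entities)) {
            expected[[length(expected) + 1]] <-
              paste(sort(cells), collapse = " ")
          }
        }
      }
      got <- as.character(apply(tri[, c("cell_xy", "cell_xw", "cell_zy")], 1,
                                function(r) paste(sort(r), collapse = " ")))
      expect_setequal(got, as.character(unlist(expected)))
      if (nrow(tri) > 0) {
        expect_equal(max(tri$candidate),
                     max(vapply(seq_len(nrow(tri)), function(i) {
                       mean(c(tri$A[i], tri$B[i], tri$C[i]))
                     }, double(1))), tolerance = 1e-12)
      }
    }
  }
})

test_that("candidate means and best-triple selection are deterministic", {
  expect_equal(candidate_level(0.9, 0.9, 0.9), 0.9)
  expect_equal(candidate_level(0.6, 0.9, 0.3), 0.6)
  expect_equal(candidate_level(1.0, 1.0, 0.0), 2 / 3, tolerance = 1e-12)

  tri <- tibble::tibble(
    pivot = "ca",
    cell_xy = c("a2|b1", "a1|b1"), cell_xw = c("a2|b3", "a1|b3"),
    cell_zy = c("a3|b1", "a3|b1"),
    A = c(0.8, 0.9), B = c(0.9, 0.9), C = c(0.9, 0.8761)
  )
  tri$candidate <- candidate_level(tri$A, tri$B, tri$C)
  best <- select_best_triple(tri)
  expect_equal(best$candidate, max(tri$candidate))  # 0.9757.. wins over 0.8667

  # exact tie: the support tuple sorting first lexicographically wins
  tie <- tibble::tibble(
    pivot = "ca",
    cell_xy = c("a2|b1", "a1|b1"), cell_xw = c("a2|b3", "a1|b3"),
    cell_zy = c("a3|b1", "a3|b1"),
    A = 0.6, B = 0.6, C = 0.6
  )
  tie$candidate <- candidate_level(tie$A, tie$B, tie$C)
  expect_equal(select_best_triple(tie)$cell_xy, "a1|b1")
  expect_error(select_best_triple(tie[0, ]), class = "netclosure_no_triples")
})

test_that("iteration semantics: synchronous staging and the 1/k penalty", {
  # single L-shape: the fourth cell appears at iteration 1 with the
  # triple mean (0.6 + 0.9 + 0.3)/3 / 1 = 0.6
  lex <- matrix_lexicon(2, 2)
  net <- network_from_interactions(lex, known_cells(
    "caxcb", "a1|b1" = 0.6, "a1|b2" = 0.9, "a2|b1" = 0.3
  ))
  out <- run_inference(net)
  new_cell <- out$cells[out$cells$status == "new", ]
  expect_equal(new_cell$entities, "a2|b2")
  expect_equal(new_cell$iteration, 1L)
  expect_equal(new_cell$level, 0.6, tolerance = 1e-12)

  # two-step chain: hand-computed levels, second-wave cell halved
  fx <- chain_fixture()
  out2 <- run_inference(network_from_interactions(fx$lexicon, fx$known))
  got <- out2$cells[out2$cells$status == "new",
                    c("entities", "iteration", "level")]
  got <- got[order(got$entities), ]
  expected <- fx$expected_new[order(fx$expected_new$entities), ]
  expect_equal(got$entities, expected$entities)
  expect_equal(got$iteration, expected$iteration)
  expect_equal(got$level, expected$level, tolerance = 1e-12)

  # fully known matrix: inference is the identity
  lexf <- matrix_lexicon(2, 2)
  full <- network_from_interactions(lexf, known_cells(
    "caxcb", "a1|b1" = 0.5, "a1|b2" = 0.5, "a2|b1" = 0.5, "a2|b2" = 0.5
  ))
  outf <- run_inference(full)
  expect_equal(outf$iterations_run, 0L)
  expect_equal(outf$cells$status, rep("known", 4))
})

test_that("inference equals the naive fixpoint oracle on random 2-D matrices", {
  set.seed(51)
  for (rep_i in 1:40) {
    n_a <- sample(2:6, 1)
    n_b <- sample(2:6, 1)
    clusters <- list(ca = sprintf("a%d", 1:n_a), cb = sprintf("b%d", 1:n_b))
    known <- random_known(clusters, density = runif(1, 0.2, 0.5))
    if (nrow(known) == 0) next
    lex <- matrix_lexicon(n_a, n_b)
    got <- package_infer(lex, known, "caxcb")
    want <- oracle_infer(clusters, known)
    expect_equal(got$entities, want$entities)
    expect_equal(got$status, want$status)
    expect_equal(got$iteration, want$iteration)
    expect_equal(got$level, want$level, tolerance = 1e-12)
  }
})

test_that("inference conserves known cells and reaches a true fixpoint", {
  set.seed(61)
  clusters <- list(ca = sprintf("a%d", 1:4), cb = sprintf("b%d", 1:4))
  known <- random_known(clusters, density = 0.4)
  lex <- matrix_lexicon(4, 4)
  net <- network_from_interactions(lex,
                                   dplyr::mutate(known, subnetwork = "caxcb"))
  out <- run_inference(net)
  # conservation
  for (i in seq_len(nrow(known))) {
    row <- out$cells[out$cells$entities == known$entities[i], ]
    expect_equal(row$status, "known")
    expect_equal(row$level, known$level[i])
  }
  # fixpoint: no remaining absent cell has a valid triple
  all_keys <- as.vector(outer(clusters$ca, clusters$cb, paste, sep = "|"))
  for (key in setdiff(all_keys, out$cells$entities)) {
    expect_equal(nrow(find_closure_triples(out, "caxcb", key)), 0)
  }
  # penalty: level = candidate / k for every new cell
  news <- out$cells[out$cells$status == "new", ]
  for (i in seq_len(nrow(news))) {
    expect_equal(news$level[i],
                 news$support[[i]]$candidate / news$iteration[i],
                 tolerance = 1e-12)
  }
})

test_that("ranking sorts by level with deterministic ties and truncation", {
  lex <- matrix_lexicon(3, 3)
  net <- network_from_interactions(lex, known_cells(
    "caxcb", "a1|b1" = 0.9, "a1|b2" = 0.5, "a2|b1" = 0.7, "a2|b2" = 0.7
  ))
  ranked <- rank_interactions(net, top_k = 2)
  expect_equal(ranked$entities, c("a1|b1", "a2|b1"))
  expect_equal(ranked$rank, 1:2)
  # tie at 0.7 resolved lexicographically
  full <- rank_interactions(net)
  expect_equal(full$entities[2:3], c("a2|b1", "a2|b2"))
  # independent sort oracle on random levels
  set.seed(71)
  known <- random_known(list(ca = sprintf("a%d", 1:3),
                             cb = sprintf("b%d", 1:3)), density = 0.9)
  net2 <- network_from_interactions(lex,
                                    dplyr::mutate(known, subnetwork = "caxcb"))
  ranked2 <- rank_interactions(net2)
  ord <- order(-known$level, known$entities)
  expect_equal(ranked2$entities, known$entities[ord])
  expect_equal(nrow(rank_interactions(net2, status = "new")), 0)
})

test_that("inference history records all candidates and the accepted one", {
  fx <- chain_fixture()
  out <- run_inference(network_from_interactions(fx$lexicon, fx$known))
  tr <- trace_history(out, "a1|b3")
  expect_s3_class(tr, "inference_trace")
  expect_equal(tr$final_iteration, 2L)
  expect_equal(tr$final_level, (0.8 + 0.6 + 0.9) / 3 / 2, tolerance = 1e-12)
  trs <- tr$iterations[[1]]$triples
  expect_gte(nrow(trs), 2)                # several candidates examined
  expect_equal(sum(trs$accepted), 1)      # exactly one accepted
  expect_equal(max(trs$candidate), trs$candidate[trs$accepted],
               tolerance = 1e-12)
  expect_equal(tr$final_level, trs$candidate[trs$accepted] / 2,
               tolerance = 1e-12)

  expect_error(trace_history(out, "a1|b1"),
               class = "netclosure_trace_not_new")
  expect_error(trace_history(out, "a1|zzz"),
               class = "netclosure_unknown_entity")

  # JSON export follows the documented schema
  f <- withr::local_tempfile(fileext = ".json")
  write_trace_json(tr, f)
  js <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  expect_equal(js$target, list("a1", "b3"))
  expect_equal(js$final_iteration, 2)
  expect_equal(length(js$iterations[[1]]$triples[[1]]$cells), 3)
})

test_that("n-dimensional closure works over pivot bipartitions", {
  # 3-D: knowns share the pivot structure only through category ca
  lex <- matrix_lexicon(2, 2, 2)
  net <- network_from_interactions(lex, known_cells(
    "caxcbxcc",
    "a1|b1|c1" = 0.9,   # (x, y)
    "a1|b2|c2" = 0.6,   # (x, w)
    "a2|b1|c1" = 0.3    # (z, y)
  ))
  out <- run_inference(net)
  new_cell <- out$cells[out$cells$status == "new", ]
  expect_equal(new_cell$entities, "a2|b2|c2")
  expect_equal(new_cell$level, (0.9 + 0.6 + 0.3) / 3, tolerance = 1e-12)
  expect_equal(new_cell$support[[1]]$pivot, "ca")
})
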