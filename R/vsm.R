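#' Normalized term frequency
#'
#' tf = f / max_f, where max_f is the frequency of the document's most
#' frequent network entity; 0 when the document contains no entity at all.
#'
#' @param f Occurrence count of the entity in the document.
#' @param max_f Count of the document's most frequent entity.
#' @return tf in \[0, 1\]. Vectorized.
#' @export
term_frequency <- function(f, max_f) {
  if (any(f > max_f)) {
    abort_input("entity frequency exceeds the document's maximal frequency",
                class = "netclosure_tf_inconsistency")
  }
  ifelse(max_f == 0, 0, f / max_f)
}

#' Inverse document frequency
#'
#' idf = log(N / n) where N is the collection size and n the number of
#' documents containing the entity.  An entity present in every document
#' gets idf 0 and therefore weight 0 everywhere.
#'
#' @param n_docs Collection size N.
#' @param n_entity Number of documents containing the entity (n > 0).
#' @param base Logarithm base; natural log by default.  The base only
#'   rescales all weights monotonically.
#' @return idf >= 0. Vectorized over `n_entity`.
#' @export
inverse_document_frequency <- function(n_docs, n_entity, base = exp(1)) {
  if (any(n_entity == 0)) {
    abort_input("idf undefined for an entity occurring in no document",
                class = "netclosure_idf_undefined_entity")
  }
  if (any(n_entity > n_docs)) {
    abort_input("entity document frequency exceeds the collection size",
                class = "netclosure_idf_inconsistency")
  }
  log(n_docs / n_entity) / log(base)
}

#' TFIDF entity weight
#'
#' @param tf Normalized term frequency in \[0, 1\].
#' @param idf Inverse document frequency, >= 0.
#' @return w = tf * idf. Vectorized.
#' @export
entity_weight <- function(tf, idf) tf * idf

#' Build the entity weight matrix
#'
#' Computes the TFIDF weight of every network entity in every document and
#' the per-document vector norms over the full entity vocabulary.  The
#' matrix is stored sparsely: absent pairs have weight 0.
#'
#' @param index An `occurrence_index` from [count_occurrences()].
#' @param idf_base Logarithm base for the idf (default natural log).
#' @return An `entity_weights` object: a list with `weights` (tibble
#'   `doc_id, entity, weight`), `norms` (tibble `doc_id, norm`), `idf`
#'   (tibble `entity, idf`), `idf_base` and `n_docs`.
#' @export
build_weight_matrix <- function(index, idf_base = exp(1)) {
  stopifnot(inherits(index, "occurrence_index"))
  idf_tbl <- index$doc_freq |>
    dplyr::filter(.data$n_docs > 0) |>
    dplyr::mutate(idf = inverse_document_frequency(index$n_docs, .data$n_docs,
                                                   base = idf_base)) |>
    dplyr::select("entity", "idf")

  weights <- index$counts |>
    dplyr::left_join(index$max_freq, by = "doc_id") |>
    dplyr::inner_join(idf_tbl, by = "entity") |>
    dplyr::mutate(weight = entity_weight(term_frequency(.data$f, .data$max_f),
                                         .data$idf)) |>
    dplyr::select("doc_id", "entity", "weight")

  norms <- weights |>
    dplyr::summarise(norm = sqrt(sum(.data$weight^2)), .by = "doc_id")
  # documents without any entity occurrence have norm 0
  missing <- setdiff(index$doc_ids, norms$doc_id)
  if (length(missing) > 0) {
    norms <- dplyr::bind_rows(norms, tibble::tibble(doc_id = missing, norm = 0))
  }
  norms <- dplyr::arrange(norms, .data$doc_id)

  structure(
    list(weights = weights, norms = norms, idf = idf_tbl,
         idf_base = idf_base, n_docs = index$n_docs),
    class = "entity_weights"
  )
}

#' @export
print.entity_weights <- function(x, ...) {
  cat(sprintf("<entity_weights> %d documents, %d nonzero weights (idf base %.4g)\n",
              x$n_docs, nrow(x$weights), x$idf_base))
  invisible(x)
}

#' @method tidy entity_weights
#' @export
tidy.entity_weights <- function(x, ...) x$weights

#' Documents satisfying an entity-conjunction query
#'
#' A cell's query is the conjunction of its entities: a document matches
#' only if every query entity occurs in it at least once.  This keeps the
#' document and query vectors non-orthogonal by construction.
#'
#' @param entities Character vector of >= 2 cluster representatives.
#' @param index An `occurrence_index`.
#' @return Sorted character vector of matching document ids.
#' @export
matching_documents <- function(entities, index) {
  stopifnot(inherits(index, "occurrence_index"))
  entities <- as.character(entities)
  unknown <- setdiff(entities, index$lexicon$representative)
  if (length(unknown) > 0) {
    abort_input(paste0("query entity not in the lexicon: ",
                       paste(unknown, collapse = ", ")),
                class = "netclosure_unknown_entity")
  }
  per_entity <- lapply(entities, function(e) {
    index$counts$doc_id[index$counts$entity == e]
  })
  sort(Reduce(intersect, per_entity), method = "radix")
}

#' Cosine similarity of a document to an entity-conjunction query
#'
#' Query weights are fixed at 1 for the query entities and 0 elsewhere, so
#' sim(d, q) = sum of the document's weights on the query entities divided
#' by (document norm over all t entities) * sqrt(|q|).  A document whose
#' norm is 0 (every contained entity ubiquitous, hence idf 0) scores 0 and
#' raises a warning.
#'
#' @param entities Character vector of query entities (>= 2).
#' @param doc_id One document id.
#' @param weights An `entity_weights` object from [build_weight_matrix()].
#' @return Similarity in \[0, 1\].
#' @export
similarity <- function(entities, doc_id, weights) {
  stopifnot(inherits(weights, "entity_weights"), length(doc_id) == 1)
  w <- weights$weights
  num <- sum(w$weight[w$doc_id == doc_id & w$entity %in% entities])
  nrm <- weights$norms$norm[weights$norms$doc_id == doc_id]
  if (length(nrm) == 0) {
    abort_input(paste0("unknown document id: ", doc_id))
  }
  if (nrm == 0) {
    warn_zero_norm(doc_id)
    return(0)
  }
  num / (nrm * sqrt(length(entities)))
}

#' Similarities of all conjunction-matching documents to a query
#'
#' @param entities Character vector of query entities (>= 2).
#' @param weights An `entity_weights` object.
#' @param index The `occurrence_index` the weights were built from.
#' @return Tibble `(doc_id, similarity)`, sorted by similarity descending,
#'   ties by document id ascending.  Empty when no document satisfies the
#'   conjunction.
#' @export
query_similarities <- function(entities, weights, index) {
  ids <- matching_documents(entities, index)
  if (length(ids) == 0) {
    return(tibble::tibble(doc_id = character(), similarity = double()))
  }
  w <- weights$weights |>
    dplyr::filter(.data$doc_id %in% ids, .data$entity %in% entities) |>
    dplyr::summarise(num = sum(.data$weight), .by = "doc_id")
  out <- tibble::tibble(doc_id = ids) |>
    dplyr::left_join(w, by = "doc_id") |>
    dplyr::left_join(weights$norms, by = "doc_id") |>
    dplyr::mutate(
      num = dplyr::coalesce(.data$num, 0),
      similarity = ifelse(.data$norm == 0, 0,
                          .data$num / (.data$norm * sqrt(length(entities))))
    )
  if (any(out$norm == 0)) warn_zero_norm(out$doc_id[out$norm == 0])
  out |>
    dplyr::select("doc_id", "similarity") |>
    dplyr::arrange(dplyr::desc(.data$similarity), .data$doc_id)
}

warn_zero_norm <- function(ids) {
  rlang::warn(
    paste0("document(s) with zero weight norm score 0: ",
           paste(unique(ids), collapse = ", ")),
    class = "netclosure_zero_norm"
  )
}

#' Dump the weight matrix as TSV (debugging aid)
#'
#' @param weights An `entity_weights` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_weights_tsv <- function(weights, path) {
  df <- weights$weights |>
    dplyr::arrange(.data$entity, .data$doc_id) |>
    dplyr::mutate(weight = sprintf("%.9f", .data$weight))
  write_tsv_bytes(df, path)
}
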