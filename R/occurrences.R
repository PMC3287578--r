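#' Count entity occurrences per document
#'
#' Detects cluster occurrences by exact phrase matching: case-insensitive,
#' on word boundaries (a match may not begin or end inside an alphanumeric
#' token), scanning each document left to right with the longest synonym
#' tried first so that nested names ("diabetes mellitus type 2" vs
#' "type 2 diabetes") are not double counted.  Matches are non-overlapping
#' within a cluster; counts are summed over a cluster's synonyms.
#'
#' The result carries every symbol the TFIDF weighting needs: the raw
#' frequencies f of each cluster in each document, each document's maximal
#' entity frequency, the collection size N and each cluster's document
#' frequency n (number of documents with at least one occurrence).
#'
#' @param docs A corpus (see [corpus()]).
#' @param lex A [lexicon()].
#' @return An `occurrence_index` object: a list with
#'   \describe{
#'     \item{counts}{tibble `(doc_id, entity, f)` of positive counts}
#'     \item{max_freq}{tibble `(doc_id, max_f)` over all documents}
#'     \item{doc_freq}{tibble `(entity, n_docs)` over all clusters}
#'     \item{n_docs}{number of documents N}
#'     \item{doc_ids}{document ids in corpus order}
#'     \item{lexicon}{the lexicon used}
#'   }
#' @export
count_occurrences <- function(docs, lex) {
  stopifnot(inherits(lex, "lexicon"))
  docs <- corpus(docs)
  if (nrow(lex) == 0) abort_input("lexicon has no clusters")

  texts <- docs$text
  counts_by_cluster <- lapply(seq_len(nrow(lex)), function(k) {
    count_phrase_matches(texts, lex$match_terms[[k]])
  })
  mat <- do.call(cbind, counts_by_cluster)  # docs x clusters
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = length(texts))
  colnames(mat) <- lex$representative

  pos <- which(mat > 0, arr.ind = TRUE)
  counts <- tibble::tibble(
    doc_id = docs$id[pos[, 1]],
    entity = lex$representative[pos[, 2]],
    f = unname(mat[pos])
  ) |>
    dplyr::arrange(.data$doc_id, .data$entity)

  max_freq <- tibble::tibble(
    doc_id = docs$id,
    max_f = if (ncol(mat) > 0) unname(apply(mat, 1, max)) else rep(0L, nrow(docs))
  )
  doc_freq <- tibble::tibble(
    entity = lex$representative,
    n_docs = unname(colSums(mat > 0))
  ) |>
    dplyr::arrange(.data$entity)

  structure(
    list(counts = counts, max_freq = max_freq, doc_freq = doc_freq,
         n_docs = nrow(docs), doc_ids = docs$id, lexicon = lex),
    class = "occurrence_index"
  )
}

# Non-overlapping, left-to-right, longest-alternative-first phrase counting.
# `terms` must already be lowercase and sorted longest first (the lexicon
# constructor guarantees this).  PCRE alternation tries alternatives in the
# listed order at each position, which gives exactly the longest-first scan.
count_phrase_matches <- function(texts, terms) {
  if (length(terms) == 0 || length(texts) == 0) {
    return(integer(length(texts)))
  }
  esc <- gsub("([.\\\\|()\\[\\]{}^$*+?])", "\\\\\\1", terms, perl = TRUE)
  pattern <- paste0("(?<![[:alnum:]])(?:", paste(esc, collapse = "|"),
                    ")(?![[:alnum:]])")
  hits <- gregexpr(pattern, texts, perl = TRUE, ignore.case = TRUE)
  vapply(hits, function(h) {
    if (length(h) == 1 && h[1] == -1L) 0L else length(h)
  }, integer(1))
}

#' @export
print.occurrence_index <- function(x, ...) {
  cat(sprintf(
    "<occurrence_index> %d documents, %d entity clusters, %d positive counts\n",
    x$n_docs, nrow(x$lexicon), nrow(x$counts)
  ))
  invisible(x)
}

#' @method tidy occurrence_index
#' @export
tidy.occurrence_index <- function(x, ...) {
  dplyr::left_join(x$counts, x$max_freq, by = "doc_id") |>
    dplyr::left_join(x$doc_freq, by = "entity")
}

# frequency of one entity in one document (0 when absent)
occurrence_count <- function(index, doc_id, entity) {
  hit <- index$counts$f[index$counts$doc_id == doc_id &
                          index$counts$entity == entity]
  if (length(hit) == 0) 0L else hit[[1]]
}
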