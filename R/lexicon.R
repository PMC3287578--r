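#' Build an entity lexicon from a data frame
#'
#' A lexicon is the controlled vocabulary of the network: entity names are
#' grouped into synonym clusters, each cluster represented by one canonical
#' name and assigned to exactly one biological category (e.g. disease, drug,
#' gene, target).  Clusters are the network nodes; the number of clusters
#' `t` is the entity-vocabulary size used throughout the vector space model.
#'
#' @param clusters A data frame with columns `representative` (character),
#'   `category` (character) and `synonyms` (list column of character
#'   vectors; may omit the representative, which is always matched).
#' @return A `lexicon`: a tibble with one row per cluster, columns
#'   `representative`, `category`, `synonyms` and `match_terms` (all names
#'   matched for the cluster, representative included, longest first).
#' @examples
#' lex <- lexicon(tibble::tibble(
#'   representative = c("aspirin", "type 2 diabetes"),
#'   category = c("drug", "disease"),
#'   synonyms = list(
#'     "acetylsalicylic acid",
#'     c("diabetes mellitus type 2", "type ii diabetes")
#'   )
#' ))
#' n_clusters(lex)
#' @export
lexicon <- function(clusters) {
  df <- tibble::as_tibble(clusters)
  if (!all(c("representative", "category") %in% names(df))) {
    abort_input("lexicon must have columns 'representative' and 'category'",
                class = "netclosure_lexicon_parse_error")
  }
  if (!"synonyms" %in% names(df)) df$synonyms <- rep(list(character()), nrow(df))
  df$representative <- as.character(df$representative)
  df$category <- as.character(df$category)
  df$synonyms <- purrr::map(df$synonyms, as.character)

  if (any(is.na(df$representative) | df$representative == "")) {
    abort_input("every cluster needs a non-empty representative name",
                class = "netclosure_lexicon_parse_error")
  }
  if (any(is.na(df$category) | df$category == "")) {
    bad <- df$representative[is.na(df$category) | df$category == ""]
    abort_input(
      paste0("cluster(s) without a category: ", paste(bad, collapse = ", ")),
      class = "netclosure_lexicon_empty_category"
    )
  }
  dup <- unique(df$representative[duplicated(tolower(df$representative))])
  if (length(dup) > 0) {
    abort_input(
      paste0("duplicate cluster representative(s): ", paste(dup, collapse = ", ")),
      class = "netclosure_lexicon_duplicate_representative"
    )
  }

  df$match_terms <- purrr::map2(df$representative, df$synonyms, function(rep, syn) {
    terms <- unique(tolower(c(rep, syn)))
    terms <- terms[terms != ""]
    terms[order(-nchar(terms), terms)]  # longest first, then alphabetical
  })

  # synonym sets of distinct clusters must be disjoint
  pool <- tibble::tibble(
    term = unlist(df$match_terms),
    representative = rep(df$representative, lengths(df$match_terms))
  )
  shared <- pool |>
    dplyr::distinct(.data$term, .data$representative) |>
    dplyr::count(.data$term) |>
    dplyr::filter(.data$n > 1)
  if (nrow(shared) > 0) {
    abort_input(
      paste0("name(s) shared by more than one cluster: ",
             paste(shared$term, collapse = ", ")),
      class = "netclosure_lexicon_shared_synonym"
    )
  }

  class(df) <- c("lexicon", class(df))
  df
}

#' Read a lexicon from a JSON file
#'
#' Expects a JSON array of objects
#' `{"representative": str, "category": str, "synonyms": [str, ...]}`.
#'
#' @param path Path to a UTF-8 JSON file.
#' @return A validated [lexicon()].
#' @export
read_lexicon <- function(path) {
  if (!file.exists(path)) {
    abort_input(paste0("lexicon file not found: ", path),
                class = "netclosure_lexicon_parse_error")
  }
  raw <- tryCatch(
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE),
    error = function(e) {
      abort_input(paste0("cannot parse lexicon JSON '", path, "': ",
                         conditionMessage(e)),
                  class = "netclosure_lexicon_parse_error")
    }
  )
  if (!is.list(raw) || length(raw) == 0) {
    abort_input(paste0("lexicon file '", path, "' holds no clusters"),
                class = "netclosure_lexicon_parse_error")
  }
  df <- tibble::tibble(
    representative = purrr::map_chr(raw, ~ as.character(.x$representative %||% NA_character_)[1]),
    category = purrr::map_chr(raw, ~ as.character(.x$category %||% NA_character_)[1]),
    synonyms = purrr::map(raw, ~ as.character(unlist(.x$synonyms)))
  )
  lexicon(df)
}

#' Write a lexicon to JSON
#'
#' Inverse of [read_lexicon()]; the representative is not repeated in the
#' synonym array.
#'
#' @param lex A [lexicon()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lex, path) {
  stopifnot(inherits(lex, "lexicon"))
  recs <- purrr::pmap(
    list(lex$representative, lex$category, lex$synonyms),
    function(rep, cat, syn) {
      list(representative = rep, category = cat,
           synonyms = as.list(setdiff(syn, rep)))
    }
  )
  jsonlite::write_json(recs, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Number of clusters (network entity-vocabulary size)
#'
#' @param lex A [lexicon()].
#' @return Integer count of clusters, the `t` of the vector space model.
#' @export
n_clusters <- function(lex) {
  stopifnot(inherits(lex, "lexicon"))
  nrow(lex)
}

#' Categories of a lexicon
#'
#' @param lex A [lexicon()].
#' @return Character vector of category names in canonical (lexicographic)
#'   order, the order used to key subnetworks and entity tuples.
#' @export
categories <- function(lex) {
  stopifnot(inherits(lex, "lexicon"))
  sort(unique(lex$category), method = "radix")
}

#' Cluster representatives grouped by category
#'
#' @param lex A [lexicon()].
#' @return Named list, one sorted character vector of representatives per
#'   category, in canonical category order.
#' @export
clusters_by_category <- function(lex) {
  stopifnot(inherits(lex, "lexicon"))
  cats <- categories(lex)
  out <- lapply(cats, function(ct) {
    sort(lex$representative[lex$category == ct], method = "radix")
  })
  names(out) <- cats
  out
}

#' Read a dated document collection from a JSON-lines file
#'
#' One record per line: `{"id": str, "date": "YYYY-MM-DD", "text": str}`.
#' Documents are returned in file order; ids must be unique, dates must be
#' real ISO-8601 calendar dates and texts non-empty.
#'
#' @param path Path to a UTF-8 JSON-lines file.
#' @return A `corpus` tibble with columns `id` (character), `date` (Date)
#'   and `text` (character).
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) {
    abort_input(paste0("corpus file not found: ", path),
                class = "netclosure_corpus_parse_error")
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(seq_along(lines), function(i) {
    tryCatch(
      jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
      error = function(e) {
        abort_input(paste0("corpus line ", i, " is not valid JSON: ",
                           conditionMessage(e)),
                    class = "netclosure_corpus_parse_error")
      }
    )
  })
  corpus(tibble::tibble(
    id = purrr::map_chr(recs, ~ as.character(.x$id %||% NA_character_)[1]),
    date = purrr::map_chr(recs, ~ as.character(.x$date %||% NA_character_)[1]),
    text = purrr::map_chr(recs, ~ as.character(.x$text %||% NA_character_)[1])
  ))
}

#' Build a validated corpus from a data frame
#'
#' @param docs A data frame with columns `id`, `date` (Date or
#'   "YYYY-MM-DD" string) and `text`.
#' @return A `corpus` tibble (columns `id`, `date`, `text`).
#' @export
corpus <- function(docs) {
  df <- tibble::as_tibble(docs)
  if (!all(c("id", "date", "text") %in% names(df))) {
    abort_input("corpus must have columns 'id', 'date' and 'text'",
                class = "netclosure_corpus_parse_error")
  }
  df <- df[, c("id", "date", "text")]
  df$id <- as.character(df$id)
  dup <- unique(df$id[duplicated(df$id)])
  if (length(dup) > 0) {
    abort_input(paste0("duplicate document id(s): ", paste(dup, collapse = ", ")),
                class = "netclosure_corpus_duplicate_id")
  }
  df$date <- parse_iso_date(df$date, df$id)
  bad_text <- is.na(df$text) | !nzchar(trimws(df$text))
  if (any(bad_text)) {
    abort_input(paste0("document(s) with empty text: ",
                       paste(df$id[bad_text], collapse = ", ")),
                class = "netclosure_corpus_empty_text")
  }
  class(df) <- c("corpus", class(df))
  df
}

# Strict ISO-8601 day parsing: "2005-13-01" and "2004-02-30" are rejected,
# not silently coerced.
parse_iso_date <- function(x, ids) {
  if (inherits(x, "Date")) return(x)
  x <- as.character(x)
  d <- as.Date(x, format = "%Y-%m-%d")
  ok <- !is.na(d) & format(d, "%Y-%m-%d") == x
  if (!all(ok)) {
    abort_input(
      paste0("unparseable ISO-8601 date(s): ",
             paste(sprintf("%s (doc %s)", x[!ok], ids[!ok]), collapse = ", ")),
      class = "netclosure_corpus_date_error"
    )
  }
  d
}

#' Keep documents issued up to the end of a year
#'
#' Used by the temporal hold-out protocol: the network is rebuilt from the
#' documents issued on or before December 31 of `last_year`, so predictions
#' can be checked against documents issued later.
#'
#' @param docs A corpus (see [corpus()]).
#' @param last_year 4-digit year; the cut is inclusive of Dec 31.
#' @return The filtered corpus, original order preserved.
#' @export
filter_by_date <- function(docs, last_year) {
  stopifnot(is.numeric(last_year), length(last_year) == 1)
  last_year <- as.integer(last_year)
  if (last_year < 1000 || last_year > 9999) {
    abort_input("last_year must be a 4-digit year")
  }
  cutoff <- as.Date(sprintf("%d-12-31", last_year))
  docs[docs$date <= cutoff, , drop = FALSE]
}

#' Write a corpus to a JSON-lines file
#'
#' @param docs A corpus (see [corpus()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(docs, path) {
  lines <- purrr::pmap_chr(
    list(docs$id, format(docs$date, "%Y-%m-%d"), docs$text),
    function(id, date, text) {
      jsonlite::toJSON(list(id = id, date = date, text = text),
                       auto_unbox = TRUE)
    }
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_input <- function(message, class = character()) {
  rlang::abort(message, class = c(class, "netclosure_input_error"))
}
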