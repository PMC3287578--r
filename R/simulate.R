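#' Configure a synthetic corpus simulation
#'
#' The generator emulates the structure the pipeline consumes: a lexicon
#' of synonym clusters grouped into categories, and a dated document
#' collection with controlled entity co-occurrences.  Known interactions
#' are planted as documents containing an entity tuple; inference targets
#' are planted as closure patterns — three documents establishing (x,y),
#' (x,w) and (z,y) while the (z,w) co-occurrence is withheld, optionally
#' to reappear in a confirming document issued in a later year.
#'
#' Filler text is drawn from a vocabulary disjoint from every lexicon
#' name, so entity counts are exactly controllable.  To keep the expected
#' known and inferable sets exact by construction, each cluster may take
#' part in at most one planted structure.
#'
#' @param categories Named integer vector: clusters per category, e.g.
#'   `c(disease = 3, drug = 3)`.
#' @param synonyms_per_cluster Alternative names per cluster (>= 0).
#' @param n_documents Total documents, planted ones included.
#' @param year_range Inclusive years for document issue dates, e.g.
#'   `c(2000, 2004)`.
#' @param planted_known List of `list(entities = c(...), n_docs = int)`:
#'   each tuple (entities of >= 2 distinct categories) co-occurs in
#'   exactly `n_docs` documents.
#' @param planted_closures List of `list(x =, z =, y =, w =,
#'   confirm_year = NULL)`: x, z are clusters of one category and y, w of
#'   another; documents {x,y}, {x,w}, {z,y} are planted, (z,w) is
#'   withheld; with `confirm_year` set, one {z,w} document is issued in
#'   that year.
#' @param filler_vocabulary_size Size of the non-entity word pool.
#' @param seed Integer seed; generation is a pure function of the config.
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(categories = c(disease = 3, drug = 3),
                              synonyms_per_cluster = 2,
                              n_documents = 30,
                              year_range = c(2000, 2004),
                              planted_known = list(),
                              planted_closures = list(),
                              filler_vocabulary_size = 200,
                              seed = 1) {
  stopifnot(length(categories) >= 1, !is.null(names(categories)),
            all(categories >= 1), synonyms_per_cluster >= 0,
            n_documents >= 1, length(year_range) == 2,
            year_range[1] <= year_range[2], filler_vocabulary_size >= 1)
  structure(
    list(categories = categories,
         synonyms_per_cluster = as.integer(synonyms_per_cluster),
         n_documents = as.integer(n_documents),
         year_range = as.integer(year_range),
         planted_known = planted_known,
         planted_closures = planted_closures,
         filler_vocabulary_size = as.integer(filler_vocabulary_size),
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' A configuration matching the four-category benchmark network
#'
#' Four categories sized 22, 22, 20 and 23 clusters — the shape whose
#' combinatorics give 11 subnetworks and 266,528 possible interactions.
#'
#' @param ... Overrides passed to [simulation_config()].
#' @return A `simulation_config`.
#' @export
benchmark_config <- function(...) {
  defaults <- list(
    categories = c(disease = 22, drug = 22, gene = 20, target = 23),
    synonyms_per_cluster = 2,
    n_documents = 200,
    year_range = c(1976L, 2005L),
    filler_vocabulary_size = 500
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_config, args)
}

#' Read a simulation config from YAML
#'
#' @param path Path to a YAML file whose keys mirror the
#'   [simulation_config()] arguments.
#' @return A `simulation_config`.
#' @export
read_simulation_config <- function(path) {
  if (!file.exists(path)) {
    abort_input(paste0("config file not found: ", path))
  }
  raw <- tryCatch(yaml::read_yaml(path), error = function(e) {
    abort_input(paste0("cannot parse YAML config '", path, "': ",
                       conditionMessage(e)))
  })
  if (!is.list(raw)) abort_input("YAML config must be a mapping")
  if (!is.null(raw$categories)) raw$categories <- unlist(raw$categories)
  if (!is.null(raw$year_range)) raw$year_range <- unlist(raw$year_range)
  if (!is.null(raw$planted_known)) {
    raw$planted_known <- lapply(raw$planted_known, function(p) {
      list(entities = as.character(unlist(p$entities)),
           n_docs = as.integer(p$n_docs %||% 1L))
    })
  }
  if (!is.null(raw$planted_closures)) {
    raw$planted_closures <- lapply(raw$planted_closures, function(p) {
      list(x = p$x, z = p$z, y = p$y, w = p$w,
           confirm_year = p$confirm_year)
    })
  }
  do.call(simulation_config, raw)
}

#' Generate a seeded lexicon and document collection
#'
#' Deterministic for a fixed config (the seed is part of the config).
#' Documents carrying a planted tuple mention each of its entities 1-3
#' times, choosing the representative or a synonym at random, so tf
#' normalization is exercised non-trivially; no unplanted cross-category
#' co-occurrence exists.  Dates are uniform within `year_range`, except
#' confirming documents which are issued in their stated year.
#'
#' @param config A [simulation_config()].
#' @return A list:
#'   \describe{
#'     \item{lexicon}{the generated [lexicon()]}
#'     \item{docs}{the generated corpus}
#'     \item{expected_known}{tibble `(subnetwork, entities)` of every cell
#'       known from the base-year documents (confirming documents
#'       excluded)}
#'     \item{expected_new}{tibble `(subnetwork, entities)` of every cell
#'       inferable from the base-year documents}
#'     \item{expected_confirmations}{tibble `(subnetwork, entities,
#'       confirm_year)` of withheld tuples that reappear later}
#'   }
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(config$seed)

  lex <- simulated_lexicon(config)
  ent_cat <- stats::setNames(lex$category, lex$representative)

  check_planted(config, lex)

  # planted documents: entity sets + issue years
  planted <- list()
  for (p in config$planted_known) {
    for (i in seq_len(p$n_docs)) {
      planted[[length(planted) + 1L]] <- list(entities = p$entities,
                                              year = NA_integer_)
    }
  }
  confirmations <- list()
  for (p in config$planted_closures) {
    planted[[length(planted) + 1L]] <- list(entities = c(p$x, p$y), year = NA)
    planted[[length(planted) + 1L]] <- list(entities = c(p$x, p$w), year = NA)
    planted[[length(planted) + 1L]] <- list(entities = c(p$z, p$y), year = NA)
    if (!is.null(p$confirm_year)) {
      planted[[length(planted) + 1L]] <- list(entities = c(p$z, p$w),
                                              year = as.integer(p$confirm_year))
      confirmations[[length(confirmations) + 1L]] <-
        list(entities = c(p$z, p$w), confirm_year = as.integer(p$confirm_year))
    }
  }
  if (length(planted) > config$n_documents) {
    abort_input(sprintf(
      "planted structures need %d documents but n_documents = %d",
      length(planted), config$n_documents),
      class = "netclosure_sim_too_many_docs")
  }

  filler_pool <- sprintf("flw%04d", seq_len(config$filler_vocabulary_size))
  n_filler <- config$n_documents - length(planted)
  years <- config$year_range[1]:config$year_range[2]

  doc_entities <- c(lapply(planted, `[[`, "entities"),
                    rep(list(character()), n_filler))
  doc_years <- vapply(seq_along(doc_entities), function(i) {
    y <- if (i <= length(planted)) planted[[i]]$year else NA_integer_
    if (is.na(y)) sample(years, 1) else as.integer(y)
  }, integer(1))

  texts <- vapply(doc_entities, function(ents) {
    simulated_text(ents, lex, filler_pool)
  }, character(1))

  docs <- corpus(tibble::tibble(
    id = sprintf("SIM%04d", seq_along(texts)),
    date = as.Date(sprintf("%d-%02d-%02d", doc_years,
                           sample(1:12, length(texts), replace = TRUE),
                           sample(1:28, length(texts), replace = TRUE))),
    text = texts
  ))

  # ground truth from the base-year documents (confirming docs excluded)
  base_mask <- doc_years <= config$year_range[2]
  specs <- enumerate_subnetworks(names(config$categories))
  expected_known <- expected_cooccurrence(doc_entities[base_mask], ent_cat,
                                          specs)
  expected_new <- purrr::map(config$planted_closures, function(p) {
    ents <- c(p$z, p$w)
    cats <- ent_cat[ents]
    ord <- order(cats, method = "radix")
    tibble::tibble(subnetwork = subnetwork_id(cats[ord]),
                   entities = cell_key(ents[ord]))
  }) |>
    purrr::list_rbind()
  if (is.null(expected_new) || nrow(expected_new) == 0) {
    expected_new <- tibble::tibble(subnetwork = character(),
                                   entities = character())
  }
  expected_conf <- purrr::map(confirmations, function(cf) {
    cats <- ent_cat[cf$entities]
    ord <- order(cats, method = "radix")
    tibble::tibble(subnetwork = subnetwork_id(cats[ord]),
                   entities = cell_key(cf$entities[ord]),
                   confirm_year = cf$confirm_year)
  }) |>
    purrr::list_rbind()
  if (is.null(expected_conf) || nrow(expected_conf) == 0) {
    expected_conf <- tibble::tibble(subnetwork = character(),
                                    entities = character(),
                                    confirm_year = integer())
  }

  list(lexicon = lex, docs = docs,
       expected_known = dplyr::arrange(expected_known, .data$subnetwork,
                                       .data$entities),
       expected_new = dplyr::arrange(expected_new, .data$subnetwork,
                                     .data$entities),
       expected_confirmations = expected_conf)
}

# local RNG scope so generation never disturbs the caller's RNG stream
restore_seed <- function(old_seed) {
  if (is.null(old_seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
}

simulated_lexicon <- function(config) {
  rows <- purrr::imap(config$categories, function(n, cat) {
    tibble::tibble(
      representative = sprintf("%s%02d", cat, seq_len(n)),
      category = cat,
      synonyms = lapply(seq_len(n), function(i) {
        if (config$synonyms_per_cluster == 0) character() else
          sprintf("%s%02d variant%s", cat, i,
                  letters[seq_len(config$synonyms_per_cluster)])
      })
    )
  })
  lexicon(purrr::list_rbind(unname(rows)))
}

check_planted <- function(config, lex) {
  ent_cat <- stats::setNames(lex$category, lex$representative)
  used <- character()
  claim <- function(ents, what) {
    unknown <- setdiff(ents, names(ent_cat))
    if (length(unknown) > 0) {
      abort_input(paste0("planted ", what, " references unknown cluster(s): ",
                         paste(unknown, collapse = ", ")),
                  class = "netclosure_sim_unknown_cluster")
    }
    clash <- intersect(ents, used)
    if (length(clash) > 0) {
      abort_input(
        paste0("cluster(s) in more than one planted structure: ",
               paste(clash, collapse = ", "),
               " (each cluster may appear in at most one structure so the",
               " expected sets are exact by construction)"),
        class = "netclosure_sim_overlap")
    }
    used <<- c(used, ents)
  }
  for (p in config$planted_known) {
    if (length(unique(ent_cat[p$entities])) != length(p$entities)) {
      abort_input("planted known tuple must use distinct categories",
                  class = "netclosure_sim_bad_tuple")
    }
    if (length(p$entities) < 2 || p$n_docs < 1) {
      abort_input("planted known tuple needs >= 2 entities and n_docs >= 1",
                  class = "netclosure_sim_bad_tuple")
    }
    claim(p$entities, "known tuple")
  }
  for (p in config$planted_closures) {
    ents <- c(p$x, p$z, p$y, p$w)
    if (anyDuplicated(ents)) {
      abort_input("closure pattern entities must be distinct",
                  class = "netclosure_sim_bad_tuple")
    }
    claim(ents, "closure pattern")
    cats <- ent_cat[ents]
    if (is.na(cats[1]) || cats[1] != cats[2] || cats[3] != cats[4] ||
        cats[1] == cats[3]) {
      abort_input(paste0("closure pattern needs x,z in one category and ",
                         "y,w in another"),
                  class = "netclosure_sim_bad_tuple")
    }
  }
}

# one document's text: each entity mentioned 1-3 times via a random name
# of its cluster, shuffled into filler words
simulated_text <- function(entities, lex, filler_pool) {
  mentions <- unlist(lapply(entities, function(e) {
    terms <- lex$match_terms[[match(e, lex$representative)]]
    rep(sample(terms, 1), sample(1:3, 1))
  }))
  filler <- sample(filler_pool, sample(8:15, 1), replace = TRUE)
  words <- c(mentions, filler)
  paste(sample(words, length(words)), collapse = " ")
}

# every subnetwork tuple fully contained in at least one document
expected_cooccurrence <- function(doc_entity_sets, ent_cat, specs) {
  out <- purrr::map(doc_entity_sets, function(ents) {
    if (length(ents) < 2) return(NULL)
    cats <- ent_cat[ents]
    purrr::map(seq_len(nrow(specs)), function(si) {
      sub_cats <- specs$categories[[si]]
      if (!all(sub_cats %in% cats)) return(NULL)
      lists <- lapply(sub_cats, function(ct) sort(ents[cats == ct],
                                                  method = "radix"))
      grid <- expand.grid(rev(lists), KEEP.OUT.ATTRS = FALSE,
                          stringsAsFactors = FALSE)
      grid <- grid[, rev(seq_along(lists)), drop = FALSE]
      tibble::tibble(
        subnetwork = specs$subnetwork[[si]],
        entities = do.call(paste, c(unname(as.list(grid)), sep = TUPLE_SEP))
      )
    }) |>
      purrr::list_rbind()
  })
  res <- purrr::list_rbind(purrr::compact(out))
  if (is.null(res) || nrow(res) == 0) {
    return(tibble::tibble(subnetwork = character(), entities = character()))
  }
  dplyr::distinct(res)
}

#' Write a simulated lexicon and corpus to disk
#'
#' @param sim Output of [generate_corpus()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the two paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lex_path <- file.path(dir, "lexicon.json")
  corpus_path <- file.path(dir, "corpus.jsonl")
  write_lexicon(sim$lexicon, lex_path)
  write_corpus(sim$docs, corpus_path)
  invisible(c(lexicon = lex_path, corpus = corpus_path))
}
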