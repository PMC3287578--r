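#' Rebuild the network on year-limited corpus slices
#'
#' For each year in `years` the network is rebuilt, by full recomputation,
#' from the documents issued on or before December 31 of that year, and
#' the closure inference is run to its fixpoint.  Slice corpora are
#' nested, so a cell known in one slice stays known in all later slices.
#'
#' @param docs A corpus (see [corpus()]).
#' @param lex A [lexicon()].
#' @param years Integer vector of years (e.g. `2003:2005`).
#' @param strategy,idf_base Passed to [build_known_network()].
#' @param max_iterations Passed to [run_inference()].
#' @return A tibble with columns `year` and `network` (list column of
#'   inferred `interaction_network` objects).
#' @export
build_year_slices <- function(docs, lex, years,
                              strategy = c("average", "maximum", "sum"),
                              idf_base = exp(1), max_iterations = 100) {
  strategy <- match.arg(strategy)
  years <- sort(as.integer(years))
  nets <- lapply(years, function(y) {
    sliced <- filter_by_date(docs, y)
    net <- build_known_network(sliced, lex, strategy = strategy,
                               idf_base = idf_base)
    run_inference(net, max_iterations = max_iterations)
  })
  tibble::tibble(year = years, network = nets)
}

#' Predictions of one slice confirmed in a later slice
#'
#' A confirmation is an entity tuple predicted as a new interaction from
#' the documents of the earlier slice that becomes a known interaction
#' once the later slice's documents are added.  Each confirmation carries
#' its level in both slices, the number of documents supporting the
#' winning triple's known cells in the earlier slice, the number of
#' newly issued documents that confirm it, and its 1-based position in
#' the earlier slice's new-interaction ranking of its subnetwork.
#'
#' @param slice_prior,slice_next Single rows of the tibble returned by
#'   [build_year_slices()] (or lists with elements `year` and `network`);
#'   `slice_prior$year < slice_next$year`.
#' @return Tibble of confirmations: `subnetwork`, `entities`,
#'   `year_prior`, `year_next`, `level_prior`, `level_next`,
#'   `supporting_docs_prior`, `confirming_docs_next`, `rank_prior`.
#' @export
find_confirmations <- function(slice_prior, slice_next) {
  prior <- slice_element(slice_prior)
  nxt <- slice_element(slice_next)
  if (prior$year >= nxt$year) {
    abort_input("slice_prior must be an earlier year than slice_next")
  }
  net_y <- prior$network
  net_n <- nxt$network

  empty <- tibble::tibble(
    subnetwork = character(), entities = character(),
    year_prior = integer(), year_next = integer(),
    level_prior = double(), level_next = double(),
    supporting_docs_prior = integer(), confirming_docs_next = integer(),
    rank_prior = integer()
  )
  new_y <- net_y$cells[net_y$cells$status == "new", ]
  known_n <- net_n$cells[net_n$cells$status == "known", ]
  hits <- dplyr::inner_join(
    dplyr::select(new_y, "subnetwork", "entities",
                  level_prior = "level", support_prior = "support"),
    dplyr::select(known_n, "subnetwork", "entities",
                  level_next = "level", support_next = "support"),
    by = c("subnetwork", "entities")
  )
  if (nrow(hits) == 0) return(empty)

  prior_doc_ids <- net_y$doc_ids
  hits$supporting_docs_prior <- vapply(seq_len(nrow(hits)), function(i) {
    tri <- hits$support_prior[[i]]
    sub <- hits$subnetwork[[i]]
    docs <- unlist(lapply(tri$cells, function(ck) {
      row <- net_y$cells[net_y$cells$subnetwork == sub &
                           net_y$cells$entities == ck, ]
      if (nrow(row) == 1 && row$status[[1]] == "known") {
        row$support[[1]]$doc_id
      } else character()
    }))
    length(unique(docs))
  }, integer(1))
  hits$confirming_docs_next <- vapply(hits$support_next, function(s) {
    sum(!(s$doc_id %in% prior_doc_ids))
  }, integer(1))

  ranks <- rank_per_subnetwork(net_y)
  hits |>
    dplyr::left_join(ranks, by = c("subnetwork", "entities")) |>
    dplyr::transmute(
      subnetwork = .data$subnetwork, entities = .data$entities,
      year_prior = prior$year, year_next = nxt$year,
      level_prior = .data$level_prior, level_next = .data$level_next,
      supporting_docs_prior = .data$supporting_docs_prior,
      confirming_docs_next = .data$confirming_docs_next,
      rank_prior = .data$rank_prior
    ) |>
    dplyr::arrange(.data$subnetwork, .data$rank_prior, .data$entities)
}

slice_element <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1)
    list(year = x$year[[1]], network = x$network[[1]])
  } else {
    stopifnot(is.list(x), !is.null(x$year), !is.null(x$network))
    list(year = as.integer(x$year), network = x$network)
  }
}

# per-subnetwork new-interaction ranking of a network
rank_per_subnetwork <- function(net) {
  tidy.interaction_network(net) |>
    dplyr::filter(.data$status == "new") |>
    dplyr::arrange(dplyr::desc(.data$level), .data$entities) |>
    dplyr::mutate(rank_prior = dplyr::row_number(), .by = "subnetwork") |>
    dplyr::select("subnetwork", "entities", "rank_prior")
}

#' Confirmations across all consecutive year slices
#'
#' @param slices Tibble from [build_year_slices()].
#' @return Tibble of confirmations over all consecutive year pairs.
#' @export
confirmations_by_year <- function(slices) {
  if (nrow(slices) < 2) {
    return(tibble::tibble(
      subnetwork = character(), entities = character(),
      year_prior = integer(), year_next = integer(),
      level_prior = double(), level_next = double(),
      supporting_docs_prior = integer(), confirming_docs_next = integer(),
      rank_prior = integer()
    ))
  }
  purrr::map(seq_len(nrow(slices) - 1), function(i) {
    find_confirmations(slices[i, ], slices[i + 1, ])
  }) |>
    purrr::list_rbind()
}

#' Top-K distribution of confirmations in the prior-year ranking
#'
#' Counts, per subnetwork, the confirmations whose rank in the prior
#' year's new-interaction ranking is within the top K, and the overall
#' percentage 100 * sum(top-K) / sum(confirmations).
#'
#' @param confs Confirmation tibble from [find_confirmations()].
#' @param k Ranking cut (default 100).
#' @return A `validation_report` object with `by_subnetwork` (tibble
#'   `subnetwork, n_confirmed, n_topk`), `k`, `n_confirmed`, `n_topk`,
#'   `pct_topk` (NA when there are no confirmations).
#' @export
topk_distribution <- function(confs, k = 100) {
  by_sub <- confs |>
    dplyr::summarise(
      n_confirmed = dplyr::n(),
      n_topk = sum(.data$rank_prior <= k),
      .by = "subnetwork"
    ) |>
    dplyr::arrange(.data$subnetwork)
  n_confirmed <- nrow(confs)
  n_topk <- sum(confs$rank_prior <= k)
  structure(
    list(by_subnetwork = by_sub, k = k, n_confirmed = n_confirmed,
         n_topk = n_topk,
         pct_topk = if (n_confirmed > 0) 100 * n_topk / n_confirmed else NA_real_,
         confirmations = confs),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %d confirmation(s); %d within top %d",
              x$n_confirmed, x$n_topk, x$k))
  if (!is.na(x$pct_topk)) cat(sprintf(" (%.1f%%)", x$pct_topk))
  cat("\n")
  invisible(x)
}

#' @method tidy validation_report
#' @export
tidy.validation_report <- function(x, ...) x$by_subnetwork

#' @method glance validation_report
#' @export
glance.validation_report <- function(x, ...) {
  tibble::tibble(k = x$k, n_confirmed = x$n_confirmed, n_topk = x$n_topk,
                 pct_topk = x$pct_topk)
}

#' Full temporal hold-out validation across aggregation strategies
#'
#' Rebuilds year slices under each strategy, collects consecutive-year
#' confirmations and their top-K membership.  The confirmation tuple set
#' is identical across strategies (statuses depend only on co-occurrence
#' and closure reachability); only the ranks differ.
#'
#' @param docs A corpus.
#' @param lex A [lexicon()].
#' @param years Integer vector of years.
#' @param strategies Aggregation strategies to sweep.
#' @param k Ranking cut (default 100).
#' @param idf_base,max_iterations Passed through.
#' @return A `temporal_validation` object: list of per-strategy
#'   `validation_report`s plus a combined `summary` tibble
#'   `(subnetwork, new_in_prior, n_confirmed, topk_<strategy>...)`.
#' @export
temporal_validation <- function(docs, lex, years,
                                strategies = c("average", "maximum", "sum"),
                                k = 100, idf_base = exp(1),
                                max_iterations = 100) {
  strategies <- match.arg(strategies, c("average", "maximum", "sum"),
                          several.ok = TRUE)
  reports <- list()
  new_counts <- NULL
  for (st in strategies) {
    slices <- build_year_slices(docs, lex, years, strategy = st,
                                idf_base = idf_base,
                                max_iterations = max_iterations)
    confs <- confirmations_by_year(slices)
    reports[[st]] <- topk_distribution(confs, k = k)
    if (is.null(new_counts) && nrow(slices) >= 2) {
      # new interactions per subnetwork in the prior slices
      new_counts <- purrr::map(seq_len(nrow(slices) - 1), function(i) {
        tidy.interaction_network(slices$network[[i]]) |>
          dplyr::filter(.data$status == "new") |>
          dplyr::count(.data$subnetwork, name = "new_in_prior")
      }) |>
        purrr::list_rbind() |>
        dplyr::summarise(new_in_prior = sum(.data$new_in_prior),
                         .by = "subnetwork")
    }
  }
  base <- reports[[1]]$by_subnetwork |>
    dplyr::select("subnetwork", "n_confirmed")
  for (st in strategies) {
    col <- reports[[st]]$by_subnetwork |>
      dplyr::select("subnetwork", "n_topk")
    names(col)[2] <- paste0("topk_", st)
    base <- dplyr::left_join(base, col, by = "subnetwork")
  }
  if (!is.null(new_counts)) {
    base <- dplyr::left_join(base, new_counts, by = "subnetwork") |>
      dplyr::relocate("new_in_prior", .after = "subnetwork")
  }
  structure(
    list(reports = reports, summary = base, k = k, strategies = strategies),
    class = "temporal_validation"
  )
}

#' @export
print.temporal_validation <- function(x, ...) {
  cat(sprintf("<temporal_validation> strategies: %s; top %d\n",
              paste(x$strategies, collapse = ", "), x$k))
  for (st in x$strategies) {
    r <- x$reports[[st]]
    cat(sprintf("  %-8s %d/%d confirmations in top %d%s\n", st,
                r$n_topk, r$n_confirmed, x$k,
                if (is.na(r$pct_topk)) "" else sprintf(" (%.1f%%)", r$pct_topk)))
  }
  invisible(x)
}

#' @method tidy temporal_validation
#' @export
tidy.temporal_validation <- function(x, ...) x$summary

#' @method glance temporal_validation
#' @export
glance.temporal_validation <- function(x, ...) {
  purrr::map(x$strategies, function(st) {
    dplyr::mutate(glance.validation_report(x$reports[[st]]), strategy = st,
                  .before = 1)
  }) |>
    purrr::list_rbind()
}

#' Export a temporal validation report as TSV + JSON
#'
#' The TSV mirrors the per-subnetwork summary (one top-K column per
#' strategy); the JSON carries the overall counts and percentages.
#'
#' @param val A `temporal_validation` object.
#' @param tsv_path,json_path Output paths.
#' @return `tsv_path`, invisibly.
#' @export
write_validation_report <- function(val, tsv_path, json_path) {
  stopifnot(inherits(val, "temporal_validation"))
  write_tsv_bytes(val$summary, tsv_path)
  overall <- lapply(val$strategies, function(st) {
    r <- val$reports[[st]]
    list(strategy = st, n_confirmed = r$n_confirmed, n_topk = r$n_topk,
         pct_topk = if (is.na(r$pct_topk)) NULL else r$pct_topk)
  })
  jsonlite::write_json(list(k = val$k, overall = overall), json_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(tsv_path)
}

#' Plot the rank distribution of confirmations
#'
#' Shows where each confirmation fell in the prior year's per-subnetwork
#' ranking, with the top-K cut marked.
#'
#' @param object A `validation_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot validation_report
#' @export
autoplot.validation_report <- function(object, ...) {
  ggplot2::ggplot(object$confirmations,
                  ggplot2::aes(x = .data$rank_prior, y = .data$subnetwork)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = object$k, linetype = "dashed") +
    ggplot2::labs(x = "rank in prior-year new-interaction ranking",
                  y = NULL,
                  title = sprintf("Confirmations and the top-%d cut", object$k)) +
    ggplot2::theme_minimal()
}
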