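#' Enumerate all subnetwork dimensional spaces
#'
#' Every combination of 2 or more distinct categories forms a subnetwork
#' (its "dimensional space"); with c categories there are 2^c - c - 1 of
#' them (4 categories: 6 pairs + 4 triples + 1 quadruple = 11).
#'
#' @param cats Character vector of >= 2 category names.
#' @return Tibble with columns `subnetwork` (id, category names joined by
#'   "x" in canonical order), `categories` (list column), `ndim`.
#' @examples
#' enumerate_subnetworks(c("disease", "drug", "gene", "target"))
#' @export
enumerate_subnetworks <- function(cats) {
  cats <- sort(unique(as.character(cats)), method = "radix")
  if (length(cats) < 2) {
    abort_input("at least 2 categories are needed to form a subnetwork")
  }
  combos <- unlist(
    lapply(2:length(cats), function(k) {
      utils::combn(cats, k, simplify = FALSE)
    }),
    recursive = FALSE
  )
  tibble::tibble(
    subnetwork = vapply(combos, subnetwork_id, character(1)),
    categories = combos,
    ndim = lengths(combos)
  ) |>
    dplyr::arrange(.data$ndim, .data$subnetwork)
}

#' Count the possible interactions of a network
#'
#' The cells of a subnetwork are the Cartesian product of its categories'
#' cluster sets; the network total is the sum over subnetworks.
#'
#' @param lex A [lexicon()].
#' @param specs Subnetwork table from [enumerate_subnetworks()]; defaults
#'   to all subnetworks of the lexicon's categories.
#' @return Total number of cells (possible interactions).
#' @export
count_possible_interactions <- function(lex, specs = NULL) {
  stopifnot(inherits(lex, "lexicon"))
  if (is.null(specs)) specs <- enumerate_subnetworks(categories(lex))
  sizes <- table(lex$category)
  unknown <- setdiff(unique(unlist(specs$categories)), names(sizes))
  if (length(unknown) > 0) {
    abort_input(paste0("category not in the lexicon: ",
                       paste(unknown, collapse = ", ")))
  }
  sum(vapply(specs$categories, function(cs) prod(sizes[cs]), double(1)))
}

#' Aggregate document similarities into a known interaction level
#'
#' @param sims Numeric vector of cosine similarities (non-empty).
#' @param strategy One of `"average"` (arithmetic mean), `"maximum"`, or
#'   `"sum"` (may exceed 1; used for ranking only).
#' @return The aggregated level.
#' @export
aggregate_level <- function(sims, strategy = c("average", "maximum", "sum")) {
  strategy <- match.arg(strategy)
  if (length(sims) == 0) {
    abort_input("a known interaction requires at least one matching document",
                class = "netclosure_empty_similarities")
  }
  switch(strategy,
         average = mean(sims),
         maximum = max(sims),
         sum = sum(sims))
}

#' Build the known-interaction network from a corpus
#'
#' For every cell of every subnetwork the cell's entity conjunction is run
#' against the collection.  Cells with at least one matching document
#' become known interactions (iteration 0) whose level aggregates the
#' matching documents' cosine similarities; all other cells stay absent
#' (value 0).  A known cell keeps its status even when its aggregate level
#' is exactly 0 (all entities ubiquitous, idf 0): status is stored
#' explicitly, never inferred from the level.
#'
#' @param docs A corpus (see [corpus()]).
#' @param lex A [lexicon()].
#' @param strategy Similarity aggregation for known levels; see
#'   [aggregate_level()].
#' @param idf_base Logarithm base for the idf weights.
#' @return An `interaction_network` object.  Its `cells` tibble has one
#'   row per non-absent cell: `subnetwork`, `entities` (tuple key, names
#'   joined by "|" in canonical category order), `status`, `level`,
#'   `iteration`, `n_support` and a `support` list column (for known
#'   cells, a tibble of `doc_id, similarity`).
#' @export
build_known_network <- function(docs, lex,
                                strategy = c("average", "maximum", "sum"),
                                idf_base = exp(1)) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(lex, "lexicon"))
  docs <- corpus(docs)
  index <- count_occurrences(docs, lex)
  weights <- build_weight_matrix(index, idf_base = idf_base)
  specs <- enumerate_subnetworks(categories(lex))

  # entities present per document, grouped by category
  pres <- index$counts |>
    dplyr::left_join(
      tibble::tibble(entity = lex$representative, category = lex$category),
      by = "entity"
    )

  cells <- purrr::pmap(
    list(specs$subnetwork, specs$categories),
    function(sub_id, cats) {
      known_cells_for_spec(sub_id, cats, pres, weights, strategy)
    }
  ) |>
    purrr::list_rbind()

  structure(
    list(
      cells = cells,
      specs = specs,
      lexicon = lex,
      clusters = clusters_by_category(lex),
      strategy = strategy,
      idf_base = idf_base,
      doc_ids = docs$id,
      n_docs = nrow(docs),
      inferred = FALSE,
      iterations_run = 0L,
      traces = list()
    ),
    class = "interaction_network"
  )
}

# all entity tuples of one subnetwork co-occurring in >= 1 document,
# with their aggregated similarity levels
known_cells_for_spec <- function(sub_id, cats, pres, weights, strategy) {
  by_doc <- pres |>
    dplyr::filter(.data$category %in% cats) |>
    dplyr::distinct(.data$doc_id, .data$category, .data$entity)
  # documents containing at least one entity of every category of the spec
  full_docs <- by_doc |>
    dplyr::distinct(.data$doc_id, .data$category) |>
    dplyr::count(.data$doc_id) |>
    dplyr::filter(.data$n == length(cats)) |>
    dplyr::pull(.data$doc_id)
  empty <- tibble::tibble(
    subnetwork = character(), entities = character(), status = character(),
    level = double(), iteration = integer(), n_support = integer(),
    support = list()
  )
  if (length(full_docs) == 0) return(empty)

  by_doc <- dplyr::filter(by_doc, .data$doc_id %in% full_docs)
  # per document, the co-occurring tuples = product of per-category entity sets
  pairs <- by_doc |>
    dplyr::group_by(.data$doc_id) |>
    dplyr::group_map(function(g, key) {
      lists <- lapply(cats, function(ct) sort(g$entity[g$category == ct],
                                              method = "radix"))
      grid <- expand.grid(rev(lists), KEEP.OUT.ATTRS = FALSE,
                          stringsAsFactors = FALSE)
      grid <- grid[, rev(seq_along(lists)), drop = FALSE]
      tibble::tibble(
        doc_id = key$doc_id,
        entities = do.call(paste, c(unname(as.list(grid)), sep = TUPLE_SEP))
      )
    }) |>
    purrr::list_rbind()

  # cosine similarity of each (tuple, matching document) pair
  nq <- length(cats)
  long <- pairs |>
    dplyr::mutate(entity = split_key(.data$entities)) |>
    tidyr::unnest("entity")
  sims <- long |>
    dplyr::left_join(weights$weights, by = c("doc_id", "entity")) |>
    dplyr::summarise(num = sum(dplyr::coalesce(.data$weight, 0)),
                     .by = c("entities", "doc_id")) |>
    dplyr::left_join(weights$norms, by = "doc_id") |>
    dplyr::mutate(similarity = ifelse(.data$norm == 0, 0,
                                      .data$num / (.data$norm * sqrt(nq))))
  if (any(sims$norm == 0)) warn_zero_norm(sims$doc_id[sims$norm == 0])

  sims |>
    dplyr::arrange(.data$entities, dplyr::desc(.data$similarity), .data$doc_id) |>
    dplyr::group_by(.data$entities) |>
    dplyr::summarise(
      level = aggregate_level(.data$similarity, strategy),
      n_support = dplyr::n(),
      support = list(dplyr::pick("doc_id", "similarity")),
      .groups = "drop"
    ) |>
    dplyr::mutate(subnetwork = sub_id, status = "known", iteration = 0L) |>
    dplyr::select("subnetwork", "entities", "status", "level", "iteration",
                  "n_support", "support") |>
    dplyr::arrange(.data$entities)
}

#' @export
print.interaction_network <- function(x, ...) {
  n_known <- sum(x$cells$status == "known")
  n_new <- sum(x$cells$status == "new")
  cat(sprintf(
    "<interaction_network> %d subnetworks, %s possible interactions\n",
    nrow(x$specs), format(count_possible_interactions(x$lexicon, x$specs),
                          big.mark = ",")
  ))
  cat(sprintf("  known: %d   new: %d   strategy: %s   inference: %s\n",
              n_known, n_new, x$strategy,
              if (x$inferred) sprintf("run (%d iterations)", x$iterations_run)
              else "not run"))
  invisible(x)
}

#' Tidy an interaction network into its cell table
#'
#' @param x An `interaction_network`.
#' @param ... Unused.
#' @return Tibble of non-absent cells: `subnetwork`, `entities`, `status`,
#'   `level`, `iteration`, `n_support`.
#' @method tidy interaction_network
#' @export
tidy.interaction_network <- function(x, ...) {
  dplyr::select(x$cells, "subnetwork", "entities", "status", "level",
                "iteration", "n_support")
}

#' One-row summary of an interaction network
#'
#' @param x An `interaction_network`.
#' @param ... Unused.
#' @return Tibble with `n_subnetworks`, `n_possible`, `n_known`, `n_new`,
#'   `n_absent`, `strategy`, `idf_base`, `iterations_run`.
#' @method glance interaction_network
#' @export
glance.interaction_network <- function(x, ...) {
  n_possible <- count_possible_interactions(x$lexicon, x$specs)
  n_known <- sum(x$cells$status == "known")
  n_new <- sum(x$cells$status == "new")
  tibble::tibble(
    n_subnetworks = nrow(x$specs),
    n_possible = n_possible,
    n_known = n_known,
    n_new = n_new,
    n_absent = n_possible - n_known - n_new,
    strategy = x$strategy,
    idf_base = x$idf_base,
    iterations_run = x$iterations_run
  )
}

#' Construct a network directly from a known-interaction table
#'
#' Bypasses the corpus and the vector space model: takes the known cells
#' and their levels as given.  Useful for studying the closure inference
#' on hand-specified or randomly generated matrices.
#'
#' @param lex A [lexicon()] (its clusters define the cell space).
#' @param known Data frame with columns `subnetwork` (id as produced by
#'   [enumerate_subnetworks()]), `entities` (tuple key, "|"-joined in
#'   canonical category order) and `level`.
#' @param strategy Label recorded on the network (default "average").
#' @return An `interaction_network` with the given cells known at
#'   iteration 0 and every other cell absent.
#' @export
network_from_interactions <- function(lex, known, strategy = "average") {
  stopifnot(inherits(lex, "lexicon"))
  known <- tibble::as_tibble(known)
  stopifnot(all(c("subnetwork", "entities", "level") %in% names(known)))
  specs <- enumerate_subnetworks(categories(lex))
  bad <- setdiff(known$subnetwork, specs$subnetwork)
  if (length(bad) > 0) {
    abort_input(paste0("unknown subnetwork id(s): ", paste(bad, collapse = ", ")))
  }
  cells <- known |>
    dplyr::mutate(status = "known", iteration = 0L,
                  n_support = 0L, support = list(NULL)) |>
    dplyr::select("subnetwork", "entities", "status", "level", "iteration",
                  "n_support", "support") |>
    dplyr::arrange(.data$subnetwork, .data$entities)
  structure(
    list(cells = cells, specs = specs, lexicon = lex,
         clusters = clusters_by_category(lex), strategy = strategy,
         idf_base = exp(1), doc_ids = character(), n_docs = 0L,
         inferred = FALSE, iterations_run = 0L, traces = list()),
    class = "interaction_network"
  )
}

#' Export a network's cells as TSV
#'
#' Columns: subnetwork (category names joined by "x"), entities (names
#' joined by "|" in category order), status, level (9 decimal places),
#' iteration, support_size.  Only non-absent cells are written unless
#' `include_absent = TRUE`.  Output is byte-deterministic.
#'
#' @param net An `interaction_network`.
#' @param path Output path.
#' @param include_absent Also enumerate absent cells (level 0)?  Off by
#'   default: the full cell space can be large.
#' @return `path`, invisibly.
#' @export
write_network_tsv <- function(net, path, include_absent = FALSE) {
  stopifnot(inherits(net, "interaction_network"))
  df <- net$cells |>
    dplyr::arrange(.data$subnetwork, .data$entities) |>
    dplyr::transmute(
      subnetwork = .data$subnetwork,
      entities = .data$entities,
      status = .data$status,
      level = fmt_level(.data$level),
      iteration = .data$iteration,
      support_size = .data$n_support
    )
  if (include_absent) {
    absent <- absent_cells_table(net) |>
      dplyr::mutate(status = "absent", level = fmt_level(0),
                    iteration = 0L, support_size = 0L)
    df <- dplyr::bind_rows(df, absent) |>
      dplyr::arrange(.data$subnetwork, .data$entities)
  }
  write_tsv_bytes(df, path)
}

# every cell of the full Cartesian product not present in net$cells
absent_cells_table <- function(net) {
  purrr::pmap(
    list(net$specs$subnetwork, net$specs$categories),
    function(sub_id, cats) {
      lists <- net$clusters[cats]
      grid <- expand.grid(rev(lists), KEEP.OUT.ATTRS = FALSE,
                          stringsAsFactors = FALSE)
      grid <- grid[, rev(seq_along(lists)), drop = FALSE]
      tibble::tibble(
        subnetwork = sub_id,
        entities = do.call(paste, c(unname(as.list(grid)), sep = TUPLE_SEP))
      )
    }
  ) |>
    purrr::list_rbind() |>
    dplyr::anti_join(net$cells, by = c("subnetwork", "entities"))
}

#' Plot interaction counts and levels per subnetwork
#'
#' @param object An `interaction_network`.
#' @param ... Unused.
#' @return A ggplot: interaction levels per subnetwork, colored by status.
#' @method autoplot interaction_network
#' @export
autoplot.interaction_network <- function(object, ...) {
  df <- tidy.interaction_network(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$subnetwork, y = .data$level,
                                   colour = .data$status)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.6) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "interaction level",
                  title = "Interaction levels by subnetwork") +
    ggplot2::theme_minimal()
}
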