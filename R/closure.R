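#' Mean level of a closure triple
#'
#' A candidate new interaction takes the arithmetic mean of the three
#' supporting interaction levels (the already-penalized stored levels of
#' the cells (x,y), (x,w) and (z,y)).
#'
#' @param a,b,c Supporting levels. Vectorized.
#' @return (a + b + c) / 3.
#' @export
candidate_level <- function(a, b, c) (a + b + c) / 3

#' Find all transitive-closure triples supporting a target cell
#'
#' The closure rule: IF x interacts with y and w AND z interacts with y,
#' THEN z may interact with w — with x, z drawn from one category and the
#' complementary dimension(s) providing y and w.  For an n-dimensional
#' subnetwork each category in turn plays the pivot role (x, z range over
#' its clusters; y, w over composite tuples of the remaining categories)
#' and all bipartitions' triples compete.  In 2-D the two bipartitions
#' yield the same triples up to role relabelling; duplicates are removed.
#'
#' @param net An `interaction_network`.
#' @param subnetwork Subnetwork id (e.g. `"disease x drug"` written as
#'   `"diseasexdrug"` — category names joined by "x").
#' @param target Entity tuple key of an absent cell ("|"-joined).
#' @param available Optional predicate `function(cells)` returning a
#'   logical over the subnetwork's non-absent cells; defaults to all.
#' @return Tibble of triples: `pivot`, `cell_xy`, `cell_xw`, `cell_zy`
#'   (support tuple keys), `A`, `B`, `C` (their levels), `candidate`.
#' @export
find_closure_triples <- function(net, subnetwork, target, available = NULL) {
  stopifnot(inherits(net, "interaction_network"))
  spec <- net$specs[net$specs$subnetwork == subnetwork, ]
  if (nrow(spec) == 0) {
    abort_input(paste0("unknown subnetwork id: ", subnetwork))
  }
  cells_sub <- net$cells[net$cells$subnetwork == subnetwork, ]
  if (target %in% cells_sub$entities) {
    abort_input(paste0("target cell is not absent: ", target))
  }
  if (!is.null(available)) cells_sub <- cells_sub[available(cells_sub), ]
  cand <- closure_candidates(cells_sub, spec$categories[[1]])
  cand |>
    dplyr::filter(.data$target == !!target) |>
    dplyr::select("pivot", "cell_xy", "cell_xw", "cell_zy",
                  "A", "B", "C", "candidate") |>
    dplyr::arrange(dplyr::desc(.data$candidate),
                   .data$cell_xy, .data$cell_xw, .data$cell_zy, .data$pivot)
}

#' Select the winning triple among candidates
#'
#' The triple with the highest mean level wins; ties break
#' lexicographically on the supporting entity tuples (then on the pivot
#' category) so inference is deterministic.
#'
#' @param triples Tibble as returned by [find_closure_triples()].
#' @return A one-row tibble, the winning triple.
#' @export
select_best_triple <- function(triples) {
  if (is.null(triples) || nrow(triples) == 0) {
    abort_input("no closure triples to select from",
                class = "netclosure_no_triples")
  }
  triples |>
    dplyr::arrange(dplyr::desc(.data$candidate),
                   .data$cell_xy, .data$cell_xw, .data$cell_zy, .data$pivot) |>
    dplyr::slice_head(n = 1)
}

# All closure triples over the current non-absent cells of one subnetwork,
# every pivot bipartition, deduplicated on the unordered support set.
# Returns columns: target, pivot, x, y, z, w, cell_xy, cell_xw, cell_zy,
# A, B, C, candidate.
closure_candidates <- function(cells_sub, cats) {
  empty <- tibble::tibble(
    target = character(), pivot = character(),
    cell_xy = character(), cell_xw = character(), cell_zy = character(),
    A = double(), B = double(), C = double(), candidate = double()
  )
  if (nrow(cells_sub) < 3) return(empty)
  per_pivot <- lapply(seq_along(cats), function(pi) {
    pivot_candidates(cells_sub, cats, pi)
  })
  cand <- purrr::list_rbind(purrr::compact(per_pivot))
  if (nrow(cand) == 0) return(empty)
  # 2-D symmetry: both bipartitions produce the same support sets
  cand |>
    dplyr::mutate(
      set_key = purrr::pmap_chr(
        list(.data$cell_xy, .data$cell_xw, .data$cell_zy),
        function(a, b, c) paste(sort(c(a, b, c), method = "radix"),
                                collapse = " ")
      )
    ) |>
    dplyr::distinct(.data$target, .data$set_key, .keep_all = TRUE) |>
    dplyr::select(-"set_key")
}

pivot_candidates <- function(cells_sub, cats, pivot_idx) {
  parts <- split_key(cells_sub$entities)
  e <- tibble::tibble(
    u = vapply(parts, `[[`, character(1), pivot_idx),
    v = vapply(parts, function(p) paste(p[-pivot_idx], collapse = TUPLE_SEP),
               character(1)),
    lvl = cells_sub$level
  )
  tri <- dplyr::inner_join(
    dplyr::rename(e, x = "u", w = "v", B = "lvl"),
    dplyr::rename(e, x = "u", y = "v", A = "lvl"),
    by = "x", relationship = "many-to-many"
  ) |>
    dplyr::filter(.data$y != .data$w) |>
    dplyr::inner_join(dplyr::rename(e, z = "u", y = "v", C = "lvl"),
                      by = "y", relationship = "many-to-many") |>
    dplyr::filter(.data$z != .data$x)
  if (nrow(tri) == 0) return(NULL)
  tri |>
    dplyr::mutate(
      pivot = cats[pivot_idx],
      target = rebuild_keys(.data$z, .data$w, pivot_idx),
      cell_xy = rebuild_keys(.data$x, .data$y, pivot_idx),
      cell_xw = rebuild_keys(.data$x, .data$w, pivot_idx),
      cell_zy = rebuild_keys(.data$z, .data$y, pivot_idx),
      candidate = candidate_level(.data$A, .data$B, .data$C)
    )
}

# reinsert the pivot entity into the composite tuple at its category slot
rebuild_keys <- function(pivot_entity, comp_key, pivot_idx) {
  comp <- split_key(comp_key)
  vapply(seq_along(pivot_entity), function(i) {
    paste(append(comp[[i]], pivot_entity[[i]], after = pivot_idx - 1L),
          collapse = TUPLE_SEP)
  }, character(1))
}

#' Run one inference iteration on a network
#'
#' Finds, for every absent cell, the closure triples over cells
#' established in earlier iterations (iteration < k); cells with at least
#' one triple become new interactions at iteration k with level = best
#' triple mean / k.  The update is synchronous: cells created at
#' iteration k never support another cell at iteration k.
#'
#' @param net An `interaction_network`.
#' @param k Iteration number, >= 1.
#' @return Tibble of the newly created cells (possibly empty), same
#'   columns as `net$cells` plus the candidate set is recorded in the
#'   attribute `"candidates"` (used for traces).
#' @export
infer_iteration <- function(net, k) {
  stopifnot(inherits(net, "interaction_network"), k >= 1)
  out <- lapply(seq_len(nrow(net$specs)), function(si) {
    sub_id <- net$specs$subnetwork[[si]]
    cats <- net$specs$categories[[si]]
    cells_sub <- net$cells[net$cells$subnetwork == sub_id &
                             net$cells$iteration < k, ]
    cand <- closure_candidates(cells_sub, cats)
    # only absent targets may transition
    occupied <- net$cells$entities[net$cells$subnetwork == sub_id]
    cand <- cand[!(cand$target %in% occupied), , drop = FALSE]
    if (nrow(cand) == 0) return(NULL)
    cand$subnetwork <- sub_id
    cand
  })
  cand_all <- purrr::list_rbind(purrr::compact(out))
  if (is.null(cand_all) || nrow(cand_all) == 0) {
    new_cells <- net$cells[0, ]
    attr(new_cells, "candidates") <- NULL
    return(new_cells)
  }
  winners <- cand_all |>
    dplyr::arrange(dplyr::desc(.data$candidate),
                   .data$cell_xy, .data$cell_xw, .data$cell_zy, .data$pivot) |>
    dplyr::slice_head(n = 1, by = c("subnetwork", "target"))
  new_cells <- winners |>
    dplyr::transmute(
      subnetwork = .data$subnetwork,
      entities = .data$target,
      status = "new",
      level = .data$candidate / k,
      iteration = as.integer(k),
      n_support = 3L,
      support = purrr::pmap(
        list(.data$pivot, .data$cell_xy, .data$cell_xw, .data$cell_zy,
             .data$A, .data$B, .data$C, .data$candidate),
        function(pivot, xy, xw, zy, A, B, C, avg) {
          list(pivot = pivot, cells = c(xy, xw, zy), levels = c(A, B, C),
               candidate = avg)
        }
      )
    ) |>
    dplyr::arrange(.data$subnetwork, .data$entities)
  attr(new_cells, "candidates") <- cand_all
  new_cells
}

#' Iterate the closure inference to its fixpoint
#'
#' Applies [infer_iteration()] for k = 1, 2, ... until an iteration adds
#' no cell or no absent cell remains.  Starting from iteration 1 the
#' winning triple mean is divided by k, so interactions found earlier
#' rank higher.  Known cells are never modified.
#'
#' @param net An `interaction_network` with known interactions established.
#' @param max_iterations Safety cap (default 100); reaching it raises a
#'   warning.
#' @param keep_traces Record, for every new cell, all candidate triples
#'   examined at its decision iteration (retrievable via
#'   [trace_history()])?  Default `TRUE`.
#' @param asynchronous Exploratory mode in which cells created within an
#'   iteration immediately support further cells of the same iteration
#'   (order-dependent; default `FALSE`, the synchronous semantics).
#' @return The network with inferred cells added and `inferred = TRUE`.
#' @export
run_inference <- function(net, max_iterations = 100, keep_traces = TRUE,
                          asynchronous = FALSE) {
  stopifnot(inherits(net, "interaction_network"))
  sizes <- table(net$lexicon$category)
  n_total <- sum(vapply(net$specs$categories, function(cs) prod(sizes[cs]),
                        double(1)))
  k <- 0L
  repeat {
    if (nrow(net$cells) >= n_total) break
    if (k >= max_iterations) {
      rlang::warn(sprintf("inference stopped at the iteration cap (%d)",
                          max_iterations),
                  class = "netclosure_iteration_cap")
      break
    }
    k <- k + 1L
    new_cells <- if (asynchronous) {
      infer_iteration_async(net, k)
    } else {
      infer_iteration(net, k)
    }
    if (nrow(new_cells) == 0) {
      k <- k - 1L
      break
    }
    if (keep_traces) {
      cand_all <- attr(new_cells, "candidates")
      for (i in seq_len(nrow(new_cells))) {
        key <- paste(new_cells$subnetwork[[i]], new_cells$entities[[i]],
                     sep = "::")
        tr <- cand_all[cand_all$subnetwork == new_cells$subnetwork[[i]] &
                         cand_all$target == new_cells$entities[[i]], ]
        win <- new_cells$support[[i]]
        tr$accepted <- tr$cell_xy == win$cells[[1]] &
          tr$cell_xw == win$cells[[2]] & tr$cell_zy == win$cells[[3]] &
          tr$pivot == win$pivot
        net$traces[[key]] <- list(list(
          k = k,
          triples = dplyr::select(tr, "pivot", "cell_xy", "cell_xw",
                                  "cell_zy", "A", "B", "C", "candidate",
                                  "accepted")
        ))
      }
    }
    attr(new_cells, "candidates") <- NULL
    net$cells <- dplyr::bind_rows(net$cells, new_cells) |>
      dplyr::arrange(.data$subnetwork, .data$entities)
  }
  net$inferred <- TRUE
  net$iterations_run <- k
  net
}

# Asynchronous variant: within iteration k, newly created cells are
# available at once; targets are processed in lexicographic order.
infer_iteration_async <- function(net, k) {
  created <- net$cells[0, ]
  cand_log <- list()
  repeat {
    snapshot <- net
    nxt <- infer_iteration_once_async(snapshot, k)
    if (is.null(nxt)) break
    net$cells <- dplyr::bind_rows(net$cells, nxt$cell) |>
      dplyr::arrange(.data$subnetwork, .data$entities)
    created <- dplyr::bind_rows(created, nxt$cell)
    cand_log[[length(cand_log) + 1L]] <- nxt$candidates
  }
  attr(created, "candidates") <-
    if (length(cand_log) > 0) purrr::list_rbind(cand_log) else NULL
  created
}

infer_iteration_once_async <- function(net, k) {
  out <- lapply(seq_len(nrow(net$specs)), function(si) {
    sub_id <- net$specs$subnetwork[[si]]
    cats <- net$specs$categories[[si]]
    cells_sub <- net$cells[net$cells$subnetwork == sub_id, ]
    cand <- closure_candidates(cells_sub, cats)
    cand <- cand[!(cand$target %in% cells_sub$entities), , drop = FALSE]
    if (nrow(cand) == 0) return(NULL)
    cand$subnetwork <- sub_id
    cand
  })
  cand_all <- purrr::list_rbind(purrr::compact(out))
  if (is.null(cand_all) || nrow(cand_all) == 0) return(NULL)
  first <- cand_all |>
    dplyr::arrange(.data$subnetwork, .data$target) |>
    dplyr::slice_head(n = 1)
  mine <- cand_all[cand_all$subnetwork == first$subnetwork &
                     cand_all$target == first$target, ]
  win <- select_best_triple(mine)
  cell <- tibble::tibble(
    subnetwork = win$subnetwork, entities = win$target, status = "new",
    level = win$candidate / k, iteration = as.integer(k), n_support = 3L,
    support = list(list(pivot = win$pivot,
                        cells = c(win$cell_xy, win$cell_xw, win$cell_zy),
                        levels = c(win$A, win$B, win$C),
                        candidate = win$candidate))
  )
  list(cell = cell, candidates = mine)
}

#' Rank network interactions by level
#'
#' @param net An `interaction_network`.
#' @param status `"all"`, `"known"` or `"new"`.
#' @param subnetworks Optional character vector of subnetwork ids to keep.
#' @param top_k Optional truncation.
#' @return Tibble `(rank, subnetwork, entities, status, level, iteration)`
#'   sorted by level descending; ties break lexicographically on the
#'   entity tuple (then subnetwork id).
#' @export
rank_interactions <- function(net, status = c("all", "known", "new"),
                              subnetworks = NULL, top_k = NULL) {
  stopifnot(inherits(net, "interaction_network"))
  status <- match.arg(status)
  df <- tidy.interaction_network(net)
  if (status != "all") df <- df[df$status == status, ]
  if (!is.null(subnetworks)) df <- df[df$subnetwork %in% subnetworks, ]
  df <- df |>
    dplyr::arrange(dplyr::desc(.data$level), .data$entities, .data$subnetwork) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1)
  if (!is.null(top_k)) df <- dplyr::slice_head(df, n = top_k)
  df
}

#' Export a ranked interaction list as TSV
#'
#' @param ranked Output of [rank_interactions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ranking_tsv <- function(ranked, path) {
  df <- ranked |>
    dplyr::transmute(
      rank = .data$rank, subnetwork = .data$subnetwork,
      entities = .data$entities, status = .data$status,
      level = fmt_level(.data$level), iteration = .data$iteration
    )
  write_tsv_bytes(df, path)
}

#' Retrieve the inference history of a new interaction
#'
#' Every candidate triple examined for the cell, the accepted one, and
#' the final level and iteration.
#'
#' @param net An inferred `interaction_network` (built with
#'   `keep_traces = TRUE`).
#' @param entities Entity tuple key ("|"-joined) or character vector of
#'   entity names.
#' @param subnetwork Subnetwork id; inferred from the entities' categories
#'   when omitted.
#' @return An `inference_trace` object.
#' @export
trace_history <- function(net, entities, subnetwork = NULL) {
  stopifnot(inherits(net, "interaction_network"))
  if (length(entities) > 1) entities <- cell_key(entities)
  if (is.null(subnetwork)) {
    ents <- split_key(entities)[[1]]
    cats <- net$lexicon$category[match(ents, net$lexicon$representative)]
    if (anyNA(cats)) {
      abort_input(paste0("entity not in the lexicon: ",
                         paste(ents[is.na(cats)], collapse = ", ")),
                  class = "netclosure_unknown_entity")
    }
    ord <- order(cats, method = "radix")
    subnetwork <- subnetwork_id(cats[ord])
    entities <- cell_key(ents[ord])
  }
  row <- net$cells[net$cells$subnetwork == subnetwork &
                     net$cells$entities == entities, ]
  if (nrow(row) == 0 || row$status[[1]] != "new") {
    abort_input(
      paste0("cell ", entities, " in ", subnetwork,
             " is not a new interaction (status: ",
             if (nrow(row) == 0) "absent" else row$status[[1]], ")"),
      class = "netclosure_trace_not_new"
    )
  }
  key <- paste(subnetwork, entities, sep = "::")
  its <- net$traces[[key]]
  if (is.null(its)) {
    abort_input("no trace recorded; run the inference with keep_traces = TRUE")
  }
  structure(
    list(subnetwork = subnetwork, target = split_key(entities)[[1]],
         iterations = its, final_level = row$level[[1]],
         final_iteration = row$iteration[[1]]),
    class = "inference_trace"
  )
}

#' @export
print.inference_trace <- function(x, ...) {
  cat(sprintf("<inference_trace> %s in %s\n", cell_key(x$target), x$subnetwork))
  for (it in x$iterations) {
    cat(sprintf("  iteration %d: %d candidate triple(s)\n",
                it$k, nrow(it$triples)))
  }
  cat(sprintf("  final level %.6f at iteration %d\n",
              x$final_level, x$final_iteration))
  invisible(x)
}

#' Export an inference trace as JSON
#'
#' Schema: `{"target": [...], "iterations": [{"k": int, "triples":
#' [{"cells": [[...],[...],[...]], "levels": [a,b,c], "average": v,
#' "accepted": bool}]}], "final_level": v, "final_iteration": k}`.
#'
#' @param trace An `inference_trace` from [trace_history()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_json <- function(trace, path) {
  stopifnot(inherits(trace, "inference_trace"))
  payload <- list(
    target = trace$target,
    iterations = lapply(trace$iterations, function(it) {
      list(
        k = it$k,
        triples = purrr::pmap(
          list(it$triples$cell_xy, it$triples$cell_xw, it$triples$cell_zy,
               it$triples$A, it$triples$B, it$triples$C,
               it$triples$candidate, it$triples$accepted),
          function(xy, xw, zy, a, b, c, avg, acc) {
            list(cells = list(split_key(xy)[[1]], split_key(xw)[[1]],
                              split_key(zy)[[1]]),
                 levels = c(a, b, c), average = avg, accepted = acc)
          }
        )
      )
    }),
    final_level = trace$final_level,
    final_iteration = trace$final_iteration
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
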