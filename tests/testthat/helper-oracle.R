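# Independent brute-force oracles.  These deliberately share no code with
# the package internals: plain loops and exhaustive enumeration only.

# --- phrase counting ---------------------------------------------------
# position-by-position scan, longest term first, non-overlapping,
# case-insensitive, word boundaries
oracle_count_phrase <- function(text, terms) {
  text <- tolower(text)
  terms <- terms[order(-nchar(terms))]
  n <- nchar(text)
  count <- 0L
  i <- 1L
  is_alnum <- function(ch) grepl("[[:alnum:]]", ch)
  while (i <= n) {
    matched <- 0L
    for (tm in terms) {
      len <- nchar(tm)
      if (i + len - 1L > n) next
      if (tolower(substr(text, i, i + len - 1L)) != tm) next
      before_ok <- i == 1L || !is_alnum(substr(text, i - 1L, i - 1L))
      after_ok <- i + len - 1L == n || !is_alnum(substr(text, i + len, i + len))
      if (before_ok && after_ok) {
        matched <- len
        break
      }
    }
    if (matched > 0L) {
      count <- count + 1L
      i <- i + matched
    } else {
      i <- i + 1L
    }
  }
  count
}

# --- closure inference -------------------------------------------------
# exhaustive quadruple-enumeration fixpoint with synchronous iterations
# clusters: named list category -> entity vector (canonical order)
# known: data frame with columns entities ("|"-joined), level
oracle_infer <- function(clusters, known, max_iter = 50) {
  cats <- names(clusters)
  full_grid <- expand.grid(rev(clusters), stringsAsFactors = FALSE)
  full_grid <- full_grid[, rev(seq_along(clusters)), drop = FALSE]
  all_keys <- apply(full_grid, 1, paste, collapse = "|")

  level <- stats::setNames(known$level, known$entities)
  iter <- stats::setNames(rep(0L, nrow(known)), known$entities)

  insert_at <- function(comp, piv, pos) {
    paste(append(comp, piv, after = pos - 1L), collapse = "|")
  }

  k <- 0L
  repeat {
    absent <- setdiff(all_keys, names(level))
    if (length(absent) == 0L || k >= max_iter) break
    k <- k + 1L
    avail <- names(level)[iter[names(level)] < k]
    added_lv <- numeric(0)
    for (key in absent) {
      parts <- strsplit(key, "|", fixed = TRUE)[[1]]
      best <- -Inf
      for (pi in seq_along(cats)) {
        z <- parts[pi]
        w <- parts[-pi]
        rem <- clusters[-pi]
        ygrid <- expand.grid(rev(rem), stringsAsFactors = FALSE)
        ygrid <- ygrid[, rev(seq_along(rem)), drop = FALSE]
        for (x in setdiff(clusters[[pi]], z)) {
          k_xw <- insert_at(w, x, pi)
          if (!(k_xw %in% avail)) next
          for (r in seq_len(nrow(ygrid))) {
            y <- as.character(unlist(ygrid[r, ]))
            if (identical(y, w)) next
            k_xy <- insert_at(y, x, pi)
            k_zy <- insert_at(y, z, pi)
            if (k_xy %in% avail && k_zy %in% avail) {
              avg <- (level[[k_xy]] + level[[k_xw]] + level[[k_zy]]) / 3
              if (avg > best) best <- avg
            }
          }
        }
      }
      if (is.finite(best)) added_lv[[key]] <- best / k
    }
    if (length(added_lv) == 0L) {
      k <- k - 1L
      break
    }
    level <- c(level, added_lv)
    iter <- c(iter, stats::setNames(rep(k, length(added_lv)), names(added_lv)))
  }

  out <- tibble::tibble(
    entities = names(level),
    status = unname(ifelse(iter[names(level)] == 0L, "known", "new")),
    iteration = unname(as.integer(iter[names(level)])),
    level = unname(level)
  )
  out[order(out$entities), ]
}

# random known-cell table over the full product of `clusters`
random_known <- function(clusters, density = 0.35) {
  grid <- expand.grid(rev(clusters), stringsAsFactors = FALSE)
  grid <- grid[, rev(seq_along(clusters)), drop = FALSE]
  keys <- apply(grid, 1, paste, collapse = "|")
  pick <- runif(length(keys)) < density
  tibble::tibble(entities = keys[pick],
                 level = round(runif(sum(pick)), 4))
}

# run the package inference on an abstract matrix and tabulate it the
# same way as the oracle
package_infer <- function(lex, known, subnetwork) {
  net <- network_from_interactions(
    lex, dplyr::mutate(known, subnetwork = subnetwork)
  )
  net <- run_inference(net, keep_traces = FALSE)
  out <- tidy(net)
  out <- out[out$subnetwork == subnetwork,
             c("entities", "status", "iteration", "level")]
  out[order(out$entities), ]
}
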