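# Shared helpers: tuple keys, subnetwork ids, deterministic TSV output.

TUPLE_SEP <- "|"

cell_key <- function(entities) paste(entities, collapse = TUPLE_SEP)

split_key <- function(key) strsplit(key, TUPLE_SEP, fixed = TRUE)

subnetwork_id <- function(cats) paste(cats, collapse = "x")

# Deterministic TSV writer: all columns pre-formatted as character, LF line
# endings, header row, no quoting.  Keeps repeated runs byte-identical.
write_tsv_bytes <- function(df, path) {
  df <- dplyr::mutate(df, dplyr::across(dplyr::everything(), as.character))
  lines <- c(
    paste(names(df), collapse = "\t"),
    if (nrow(df) > 0) do.call(paste, c(unname(as.list(df)), sep = "\t"))
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

fmt_level <- function(x) sprintf("%.9f", x)
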