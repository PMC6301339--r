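#' Curation history store
#'
#' An append-only log of processed publications per query. Once a pmid is
#' marked processed under a query key (gene accession + axis), subsequent
#' [triage()] runs with the same key omit it; the same pmid is still returned
#' for a different gene or axis. Status transitions are monotone:
#' `not_done -> partial -> completed`, never backwards.
#'
#' @return an object of class `curation_history`: a tibble log with columns
#'   `query_key`, `pmid`, `status`, `time`.
#' @export
curation_history <- function() {
  structure(
    tibble(query_key = character(), pmid = character(),
           status = character(), time = character()),
    class = c("curation_history", class(tibble()))
  )
}

.status_levels <- c(not_done = 0L, partial = 1L, completed = 2L)

#' Mark a publication as processed for a query
#'
#' @param history a [curation_history()].
#' @param query the [triage_query()] the pmid was returned for.
#' @param pmid the publication id.
#' @param status `"partial"` or `"completed"` (a `"not_done"` entry is legal
#'   but does not hide the pmid from future searches).
#' @return the updated history (a new object; the log is append-only).
#' @export
mark_processed <- function(history, query, pmid, status = "completed") {
  stopifnot(inherits(history, "curation_history"))
  if (!status %in% names(.status_levels)) {
    abort(paste0("unknown status \"", status, "\""))
  }
  key <- query_key(query)
  cur <- current_status(history, key, pmid)
  if (!is.na(cur) && .status_levels[[status]] < .status_levels[[cur]]) {
    abort(sprintf("status regression for %s/%s: %s -> %s", key, pmid, cur,
                  status))
  }
  entry <- tibble(query_key = key, pmid = as.character(pmid), status = status,
                  time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  out <- bind_rows(history, entry)
  structure(out, class = c("curation_history", class(tibble())))
}

# latest status for (key, pmid), NA if never seen
current_status <- function(history, key, pmid) {
  hit <- history$status[history$query_key == key & history$pmid == pmid]
  if (length(hit)) tail(hit, 1L) else NA_character_
}

# pmids hidden from future triage runs under `key` (any processed status
# above not_done)
processed_pmids <- function(history, key) {
  rows <- history[history$query_key == key, , drop = FALSE]
  if (nrow(rows) == 0L) return(character())
  last <- rows |>
    group_by(.data$pmid) |>
    summarise(status = tail(.data$status, 1L), .groups = "drop")
  last$pmid[.status_levels[last$status] > 0L]
}

#' Write / read a curation history as append-only JSONL
#'
#' Each log entry is one JSON object per line; replaying the log reconstructs
#' the processed set exactly.
#'
#' @param history a [curation_history()].
#' @param path file path.
#' @return `write_history`: `path`, invisibly. `read_history`: a
#'   `curation_history`.
#' @export
write_history <- function(history, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(history))) {
    writeLines(jsonlite::toJSON(as.list(history[i, ]), auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' @rdname write_history
#' @export
read_history <- function(path) {
  h <- curation_history()
  if (!file.exists(path)) return(h)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(h)
  rows <- purrr::map(lines, function(ln) {
    as_tibble(jsonlite::fromJSON(ln, simplifyVector = TRUE))
  })
  out <- bind_rows(h, bind_rows(rows))
  structure(out, class = c("curation_history", class(tibble())))
}
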