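#' Extract ontology-concept mentions from a document
#'
#' Dictionary matching over the normalized token streams of title and
#' abstract. All token windows up to the lexicon's longest surface form are
#' looked up in the surface index; overlaps within a section are resolved by
#' taking longer spans first, then leftmost (so "regulation of cell cycle"
#' beats "cell cycle"). An ambiguous surface form (one key, several concept
#' ids) yields one mention per candidate id, all sharing the same offsets and
#' flagged `ambiguous = TRUE`. Blacklisted concepts are still extracted —
#' filtering happens downstream at proposal time so evaluation can count them.
#'
#' @param doc a one-row corpus tibble (columns `pmid`, `title`, `abstract`).
#' @param lexicon a lexicon with its surface index built.
#' @param include_title match in the title as well as the abstract (default
#'   `TRUE`).
#' @return a tibble with columns `pmid`, `concept_id`, `matched_surface`,
#'   `section` (`"title"` or `"abstract"`), `start`, `end` (0-based half-open
#'   offsets into the section text), `sentence_index` (0-based) and
#'   `ambiguous`.
#' @export
extract_mentions <- function(doc, lexicon, include_title = TRUE) {
  stopifnot(is.data.frame(doc), nrow(doc) == 1L, inherits(lexicon, "lexicon"))
  sections <- if (include_title) c("title", "abstract") else "abstract"
  out <- purrr::map(sections, function(sec) {
    match_section(doc$pmid, doc[[sec]], sec, lexicon$surface_index,
                  lexicon$max_key_tokens)
  })
  res <- bind_rows(out)
  if (nrow(res) == 0L) empty_mentions() else res
}

empty_mentions <- function() {
  tibble(
    pmid = character(), concept_id = character(),
    matched_surface = character(), section = character(),
    start = integer(), end = integer(),
    sentence_index = integer(), ambiguous = logical()
  )
}

# Core matcher for one section: enumerate all token-window matches, then
# resolve overlaps longest-span-first with leftmost as tie-break.
match_section <- function(pmid, text, section, index, max_key_tokens) {
  toks <- normalize_tokens(text)
  n <- nrow(toks)
  if (n == 0L || max_key_tokens == 0L) return(empty_mentions())
  cand <- list()
  for (i in seq_len(n)) {
    for (len in seq_len(min(max_key_tokens, n - i + 1L))) {
      key <- paste(toks$surface[i:(i + len - 1L)], collapse = " ")
      ids <- index[[key]]
      if (!is.null(ids)) {
        cand[[length(cand) + 1L]] <- list(
          i = i, len = len, start = toks$start[i],
          end = toks$end[i + len - 1L], ids = ids
        )
      }
    }
  }
  if (length(cand) == 0L) return(empty_mentions())
  ord <- order(-vapply(cand, `[[`, integer(1), "len"),
               vapply(cand, `[[`, integer(1), "i"))
  taken <- logical(n)
  kept <- list()
  for (j in ord) {
    m <- cand[[j]]
    span <- m$i:(m$i + m$len - 1L)
    if (!any(taken[span])) {
      taken[span] <- TRUE
      kept[[length(kept) + 1L]] <- m
    }
  }
  # report in text order
  kept <- kept[order(vapply(kept, `[[`, integer(1), "start"))]
  sentences <- split_sentences(text)
  rows <- purrr::map(kept, function(m) {
    tibble(
      pmid = pmid,
      concept_id = m$ids,
      matched_surface = stringi::stri_sub(text, m$start + 1L, m$end),
      section = section,
      start = m$start,
      end = m$end,
      sentence_index = sentence_index_at(sentences, m$start),
      ambiguous = length(m$ids) > 1L
    )
  })
  bind_rows(rows)
}

#' Distinct concepts of a document in first-occurrence order
#'
#' @param mentions a mentions tibble from [extract_mentions()] (one document).
#' @return character vector of unique concept ids ordered by first occurrence,
#'   title before abstract.
#' @export
distinct_concepts <- function(mentions) {
  if (nrow(mentions) == 0L) return(character())
  ord <- order(match(mentions$section, c("title", "abstract")), mentions$start)
  unique(mentions$concept_id[ord])
}

#' Find mentions of one gene in a document
#'
#' Runs the same matcher as [extract_mentions()] over a gene entry's surface
#' forms (symbol plus synonyms); every match resolves to the gene's accession.
#'
#' @param doc a one-row corpus tibble.
#' @param gene a list with `accession`, `symbol`, `synonyms` (see
#'   [gene_entry()]).
#' @param include_title match in the title as well (default `TRUE`).
#' @return a mentions tibble whose `concept_id` is the gene accession.
#' @export
find_gene_mentions <- function(doc, gene, include_title = TRUE) {
  forms <- unique(c(gene$symbol, gene$synonyms))
  keys <- unique(surface_key(forms))
  keys <- keys[nzchar(keys)]
  if (length(keys) == 0L) return(empty_mentions())
  index <- setNames(rep(list(gene$accession), length(keys)), keys)
  max_len <- max(stringi::stri_count_fixed(keys, " ") + 1L)
  sections <- if (include_title) c("title", "abstract") else "abstract"
  res <- bind_rows(purrr::map(sections, function(sec) {
    match_section(doc$pmid, doc[[sec]], sec, index, max_len)
  }))
  if (nrow(res) == 0L) empty_mentions() else res
}

#' Serialize mentions to TSV
#'
#' @param mentions a mentions tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mentions_tsv <- function(mentions, path) {
  readr::write_tsv(
    mentions[, c("pmid", "concept_id", "section", "start", "end",
                 "sentence_index", "matched_surface")],
    path, progress = FALSE
  )
  invisible(path)
}
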