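# In-code fixture builders shared across test files.

# lexicon from a named list: id -> list(label, synonyms, parents, obsolete)
fixture_lexicon <- function(entries, axis = "BP") {
  concepts <- tibble::tibble(
    id = names(entries),
    preferred_label = vapply(entries, function(e) e$label, character(1)),
    synonyms = lapply(entries, function(e) e$synonyms %||% character()),
    parent_ids = lapply(entries, function(e) e$parents %||% character()),
    obsolete = vapply(entries, function(e) isTRUE(e$obsolete), logical(1))
  )
  new_lexicon(concepts, axis)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fixture_doc <- function(pmid, title = "", abstract = "", year = 2010L) {
  tibble::tibble(pmid = pmid, title = title, abstract = abstract,
                 year = as.integer(year), journal = NA_character_)
}

fixture_corpus <- function(...) {
  dplyr::bind_rows(...)
}

# small GO-flavoured lexicon used in several files
go_cycle_lexicon <- function() {
  fixture_lexicon(list(
    "GO:0007049" = list(label = "cell cycle", parents = "GO:0008150"),
    "GO:0051726" = list(label = "regulation of cell cycle",
                        parents = "GO:0007049"),
    "GO:0006914" = list(label = "autophagy", parents = "GO:0008150"),
    "GO:0006915" = list(label = "apoptotic process",
                        synonyms = "apoptosis", parents = "GO:0008150"),
    "GO:0008150" = list(label = "biological process")
  ))
}

fixture_gene <- function(symbol = "ZAP70", accession = "NX_P43403",
                         synonyms = character()) {
  list(accession = accession, symbol = symbol, synonyms = synonyms)
}

# decision tibble builder: one curator over pmids with given relevance and
# concept sets
fixture_decisions <- function(curator, pmids, relevant,
                              concepts = NULL, axis = "BP") {
  if (is.null(concepts)) {
    concepts <- rep(list(character()), length(pmids))
  }
  tibble::tibble(curator_id = curator, pmid = pmids, axis = axis,
                 relevant = relevant, concepts = concepts)
}

# write an OBO text fixture to a temp file, return path
write_obo_fixture <- function(text) {
  path <- withr::local_tempfile(fileext = ".obo",
                                .local_envir = parent.frame())
  writeLines(text, path)
  path
}
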