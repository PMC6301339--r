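#' Read a JSONL abstract corpus
#'
#' One JSON object per line with keys `pmid`, `title`, `abstract` and optional
#' `year`, `journal`. Records missing `abstract` are kept with an empty
#' abstract (a warning is emitted); a duplicated pmid is an error naming the
#' offending lines.
#'
#' @param path path to a JSONL file.
#' @return a tibble with columns `pmid` (character), `title`, `abstract`,
#'   `year` (integer, `NA` when absent), `journal`.
#' @export
read_corpus_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- purrr::imap(lines, function(ln, i) {
    rec <- tryCatch(
      jsonlite::fromJSON(ln, simplifyVector = TRUE),
      error = function(e) abort(sprintf("%s: malformed JSON on line %d: %s",
                                        path, i, conditionMessage(e)))
    )
    if (is.null(rec$pmid) || !nzchar(as.character(rec$pmid))) {
      abort(sprintf("%s: record on line %d has no pmid", path, i))
    }
    if (is.null(rec$abstract)) {
      warn(sprintf("%s: line %d (pmid %s) has no abstract; treated as empty",
                   path, i, rec$pmid))
    }
    tibble(
      pmid = as.character(rec$pmid),
      title = as.character(rec$title %||% ""),
      abstract = as.character(rec$abstract %||% ""),
      year = if (is.null(rec$year)) NA_integer_ else as.integer(rec$year),
      journal = as.character(rec$journal %||% NA_character_)
    )
  })
  corpus <- bind_rows(recs)
  dup <- corpus$pmid[duplicated(corpus$pmid)]
  if (length(dup)) {
    where <- vapply(unique(dup), FUN.VALUE = character(1), function(p) {
      paste0(p, " (lines ", paste(which(corpus$pmid == p), collapse = ", "), ")")
    })
    abort(paste0(path, ": duplicated pmid: ", paste(where, collapse = "; ")))
  }
  validate_corpus(corpus)
}

validate_corpus <- function(corpus) {
  bad_year <- !is.na(corpus$year) & (corpus$year < 1800L | corpus$year > 2100L)
  if (any(bad_year)) {
    abort(paste0("implausible year for pmid ",
                 paste(corpus$pmid[bad_year], collapse = ", ")))
  }
  corpus
}

#' Read a PubMed/MEDLINE XML corpus
#'
#' Maps each `PubmedArticle` record to one document: `PMID`, `ArticleTitle`,
#' the concatenation of all `AbstractText` sections (joined by one space) and
#' the publication year (from `PubDate/Year`, falling back to the first
#' four-digit run of `PubDate/MedlineDate`). Records without a PMID are
#' skipped with a warning.
#'
#' @param path path to a PubMed XML file.
#' @return a tibble as for [read_corpus_jsonl()].
#' @export
read_pubmed_xml <- function(path) {
  doc <- xml2::read_xml(path)
  arts <- xml2::xml_find_all(doc, ".//PubmedArticle")
  recs <- purrr::map(arts, function(a) {
    pmid <- xml2::xml_text(xml2::xml_find_first(a, ".//MedlineCitation/PMID"))
    if (is.na(pmid) || !nzchar(pmid)) {
      warn("PubmedArticle record without PMID skipped")
      return(NULL)
    }
    title <- xml2::xml_text(xml2::xml_find_first(a, ".//ArticleTitle"))
    abst <- xml2::xml_find_all(a, ".//Abstract/AbstractText")
    abstract <- paste(trimws(xml2::xml_text(abst)), collapse = " ")
    yr <- xml2::xml_text(xml2::xml_find_first(
      a, ".//Article//JournalIssue/PubDate/Year"))
    if (is.na(yr)) {
      md <- xml2::xml_text(xml2::xml_find_first(
        a, ".//Article//JournalIssue/PubDate/MedlineDate"))
      yr <- stringi::stri_extract_first_regex(md, "\\d{4}")
    }
    journal <- xml2::xml_text(xml2::xml_find_first(a, ".//Journal/Title"))
    tibble(
      pmid = pmid,
      title = if (is.na(title)) "" else title,
      abstract = abstract,
      year = suppressWarnings(as.integer(yr)),
      journal = journal
    )
  })
  validate_corpus(bind_rows(recs))
}

#' Tokenize text with offset preservation
#'
#' Tokens are maximal alphanumeric runs (Unicode letters and digits); hyphens,
#' en-dashes and all other punctuation act as separators. Each token surface
#' is the NFKC compatibility-normalized, case-folded form of the matched
#' substring, while `start`/`end` are 0-based half-open character offsets into
#' the original, un-normalized text — so `"T-cell"` and `"T cell"` yield the
#' same surfaces but each points back at its own source characters.
#'
#' @param text a single string (may be empty).
#' @return a tibble with columns `surface`, `start`, `end`.
#' @export
normalize_tokens <- function(text) {
  if (length(text) != 1L) abort("`text` must be a single string")
  if (is.na(text) || !nzchar(text)) {
    return(tibble(surface = character(), start = integer(), end = integer()))
  }
  loc <- stringi::stri_locate_all_regex(text, "[\\p{L}\\p{N}]+")[[1]]
  if (is.na(loc[1, 1])) {
    return(tibble(surface = character(), start = integer(), end = integer()))
  }
  raw <- stringi::stri_sub(text, loc[, 1], loc[, 2])
  tibble(
    surface = norm_fold(raw),
    start = as.integer(loc[, 1] - 1L),
    end = as.integer(loc[, 2])
  )
}

# abbreviations that suppress a sentence split when they end the left context
.sentence_abbrev_re <- "(?i)\\b(e\\.g|i\\.e|et al|vs|fig)\\.$"

#' Split text into sentence spans
#'
#' Splits on `.`, `!` or `?` followed by whitespace and an uppercase letter or
#' digit; a short abbreviation list (`e.g.`, `i.e.`, `et al.`, `vs.`, `Fig.`)
#' suppresses splits. Spans are 0-based half-open, contiguous and
#' non-overlapping, cover all non-whitespace text, and exclude boundary
#' whitespace.
#'
#' @param text a single string.
#' @return a tibble with columns `start`, `end` (one row per sentence).
#' @export
split_sentences <- function(text) {
  if (length(text) != 1L) abort("`text` must be a single string")
  empty <- tibble(start = integer(), end = integer())
  if (is.na(text) || !nzchar(trimws(text))) return(empty)
  loc <- stringi::stri_locate_all_regex(text, "[.!?](?=\\s+[A-Z0-9])")[[1]]
  breaks <- integer()
  if (!is.na(loc[1, 1])) {
    for (p in loc[, 1]) {
      left <- stringi::stri_sub(text, 1L, p)
      if (!stringi::stri_detect_regex(left, .sentence_abbrev_re)) {
        breaks <- c(breaks, p) # sentence ends at (and includes) position p
      }
    }
  }
  seg_start <- c(1L, breaks + 1L)
  seg_end <- c(breaks, stringi::stri_length(text))
  spans <- purrr::map2(seg_start, seg_end, function(s, e) {
    if (s > e) return(NULL)
    seg <- stringi::stri_sub(text, s, e)
    lead <- stringi::stri_locate_first_regex(seg, "\\S")[1]
    if (is.na(lead)) return(NULL)
    trail <- stringi::stri_locate_last_regex(seg, "\\S")[1]
    tibble(start = as.integer(s + lead - 2L), end = as.integer(s + trail - 1L))
  })
  out <- bind_rows(spans)
  if (nrow(out) == 0L) empty else out
}

# sentence index (0-based) containing character offset `pos` (0-based)
sentence_index_at <- function(sentences, pos) {
  if (nrow(sentences) == 0L) return(NA_integer_)
  hit <- which(sentences$start <= pos & pos < sentences$end)
  if (length(hit)) return(hit[1] - 1L)
  # between-sentence positions (whitespace/punctuation): nearest preceding span
  prev <- which(sentences$start <= pos)
  if (length(prev)) tail(prev, 1L) - 1L else 0L
}

#' Corpus-level statistics for the retrieval scorers
#'
#' Computes the document count `N`, the mean token count per document `avgdl`
#' (over title + abstract), per-term document frequencies `df` over normalized
#' tokens, and — when a lexicon is supplied — per-concept document frequencies
#' `concept_df` from the dictionary matcher's distinct concepts per document.
#'
#' @param corpus a corpus tibble ([read_corpus_jsonl()]).
#' @param lexicon optional lexicon; required for `concept_df`.
#' @return an object of class `corpus_stats`: a list with `N`, `avgdl`, `df`
#'   (named integer vector) and `concept_df` (named integer vector, possibly
#'   empty).
#' @export
compute_corpus_stats <- function(corpus, lexicon = NULL) {
  if (!is.data.frame(corpus) || nrow(corpus) == 0L) {
    abort("corpus is empty: statistics are undefined")
  }
  doc_terms <- purrr::map(seq_len(nrow(corpus)), function(i) {
    c(normalize_tokens(corpus$title[i])$surface,
      normalize_tokens(corpus$abstract[i])$surface)
  })
  dl <- lengths(doc_terms)
  df_tab <- table(unlist(lapply(doc_terms, unique), use.names = FALSE))
  df <- setNames(as.integer(df_tab), names(df_tab))
  concept_df <- integer()
  if (!is.null(lexicon)) {
    per_doc <- purrr::map(seq_len(nrow(corpus)), function(i) {
      unique(extract_mentions(corpus[i, ], lexicon)$concept_id)
    })
    cd_tab <- table(unlist(per_doc, use.names = FALSE))
    concept_df <- setNames(as.integer(cd_tab), names(cd_tab))
  }
  structure(
    list(N = nrow(corpus), avgdl = mean(dl), df = df, concept_df = concept_df),
    class = "corpus_stats"
  )
}

#' @export
print.corpus_stats <- function(x, ...) {
  cat(sprintf("<corpus_stats> N=%d, avgdl=%.2f, %d terms, %d concepts\n",
              x$N, x$avgdl, length(x$df), length(x$concept_df)))
  invisible(x)
}
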