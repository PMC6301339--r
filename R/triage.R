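#' Construct a triage query
#'
#' A query asks: which abstracts should a curator read for this gene on this
#' annotation axis? Optional boost keywords join the BM25 term set; excluded
#' keywords, excluded pmids and the date window filter the candidate set.
#'
#' @param gene a gene entry: list with `accession`, `symbol`, `synonyms`.
#' @param axis `"BP"` or `"D"`.
#' @param boost_keywords,excluded_keywords character vectors of keywords.
#' @param excluded_pmids character vector of pmids never to return.
#' @param date_from,date_to optional year bounds (inclusive).
#' @param max_results maximum number of ranked results (default 50).
#' @return an object of class `triage_query`.
#' @export
triage_query <- function(gene, axis, boost_keywords = character(),
                         excluded_keywords = character(),
                         excluded_pmids = character(),
                         date_from = NULL, date_to = NULL,
                         max_results = 50L) {
  assert_axis(axis)
  stopifnot(is.list(gene), !is.null(gene$accession), !is.null(gene$symbol))
  if (max_results < 1L) abort("`max_results` must be >= 1")
  if (!is.null(date_from) && !is.null(date_to) && date_from > date_to) {
    abort("`date_from` must be <= `date_to`")
  }
  structure(
    list(
      gene = gene, axis = axis,
      boost_keywords = boost_keywords,
      excluded_keywords = excluded_keywords,
      excluded_pmids = as.character(excluded_pmids),
      date_from = date_from, date_to = date_to,
      max_results = as.integer(max_results)
    ),
    class = "triage_query"
  )
}

# history key: gene accession + axis; exclusion keywords do not change the key
query_key <- function(query) {
  paste(query$gene$accession, query$axis, sep = "|")
}

#' Score weights for the triage combination
#'
#' The final triage score is a linear combination of three components:
#' BM25 relevance of the query terms, the document's concept range (how many
#' distinct axis concepts it mentions, relative to the richest candidate) and
#' a concept TF-IDF score. The production weighting behind this design was
#' never published, so the default is an equal weighting, overridable per
#' axis. `k1` and `b` are the usual Okapi BM25 saturation and
#' length-normalization parameters.
#'
#' @param w_bm25,w_range,w_tfidf non-negative component weights (must not all
#'   be zero).
#' @param k1 BM25 term-frequency saturation (default 1.2).
#' @param b BM25 length normalization in `[0, 1]` (default 0.75).
#' @return an object of class `score_weights`.
#' @export
score_weights <- function(w_bm25 = 1 / 3, w_range = 1 / 3, w_tfidf = 1 / 3,
                          k1 = 1.2, b = 0.75) {
  if (any(c(w_bm25, w_range, w_tfidf) < 0)) abort("weights must be >= 0")
  if (w_bm25 + w_range + w_tfidf <= 0) abort("at least one weight must be > 0")
  if (k1 < 0) abort("`k1` must be >= 0")
  if (b < 0 || b > 1) abort("`b` must be in [0, 1]")
  structure(
    list(w_bm25 = w_bm25, w_range = w_range, w_tfidf = w_tfidf, k1 = k1, b = b),
    class = "score_weights"
  )
}

#' Okapi BM25 score of a document for a set of query terms
#'
#' Computes `sum over t of idf(t) * f(t,d)*(k1+1) / (f(t,d) + k1*(1 - b +
#' b*|d|/avgdl))` with the +1-smoothed Robertson idf `idf(t) = ln(1 + (N -
#' df(t) + 0.5) / (df(t) + 0.5))`, which is non-negative even for terms in
#' more than half the corpus. Query terms are normalized with the corpus
#' tokenizer; terms absent from the corpus contribute 0.
#'
#' @param query_terms character vector of query terms (multi-word terms are
#'   split by the tokenizer).
#' @param doc a one-row corpus tibble.
#' @param stats a [compute_corpus_stats()] object for the candidate corpus.
#' @param k1,b BM25 parameters.
#' @return a non-negative number.
#' @export
bm25_score <- function(query_terms, doc, stats, k1 = 1.2, b = 0.75) {
  stopifnot(inherits(stats, "corpus_stats"))
  q <- unlist(lapply(query_terms, function(t) normalize_tokens(t)$surface),
              use.names = FALSE)
  q <- unique(q)
  if (length(q) == 0L) {
    warn("empty query term list; BM25 score is 0")
    return(0)
  }
  d <- c(normalize_tokens(doc$title)$surface,
         normalize_tokens(doc$abstract)$surface)
  dl <- length(d)
  f <- table(d)
  score <- 0
  for (t in q) {
    df_t <- if (t %in% names(stats$df)) stats$df[[t]] else 0L
    if (df_t == 0L) next # term absent from the corpus contributes 0
    ft <- if (t %in% names(f)) as.numeric(f[[t]]) else 0
    if (ft == 0) next
    idf <- log(1 + (stats$N - df_t + 0.5) / (df_t + 0.5))
    score <- score + idf * ft * (k1 + 1) / (ft + k1 * (1 - b + b * dl / stats$avgdl))
  }
  score
}

#' Concept-range score of a document
#'
#' The number of distinct axis concepts the document mentions, divided by the
#' maximum distinct-concept count over the current candidate set (0 when the
#' maximum is 0). Already scaled to `[0, 1]`.
#'
#' @param doc a one-row corpus tibble.
#' @param lexicon the axis lexicon.
#' @param max_distinct maximum distinct-concept count over the candidate set.
#' @return a number in `[0, 1]`.
#' @export
concept_range_score <- function(doc, lexicon, max_distinct) {
  if (max_distinct <= 0) return(0)
  k <- length(distinct_concepts(extract_mentions(doc, lexicon)))
  k / max_distinct
}

#' Concept TF-IDF score of a document
#'
#' `sum over distinct axis concepts c of tf(c, d) * ln(N / concept_df(c))`
#' where `tf` is the mention count of `c` in the document. A concept missing
#' from `concept_df` means the statistics are stale and is an error.
#'
#' @param doc a one-row corpus tibble.
#' @param lexicon the axis lexicon.
#' @param stats a [compute_corpus_stats()] object with `concept_df` (built
#'   with the same lexicon).
#' @return a non-negative number.
#' @export
tfidf_doc_score <- function(doc, lexicon, stats) {
  stopifnot(inherits(stats, "corpus_stats"))
  m <- extract_mentions(doc, lexicon)
  if (nrow(m) == 0L) return(0)
  tf <- table(m$concept_id)
  score <- 0
  for (cid in names(tf)) {
    df_c <- if (cid %in% names(stats$concept_df)) stats$concept_df[[cid]]
            else 0L
    if (df_c == 0L) {
      abort(paste0("concept ", cid, " has no document frequency: ",
                   "corpus statistics are stale"))
    }
    score <- score + as.numeric(tf[[cid]]) * log(stats$N / df_c)
  }
  score
}

# does the normalized token sequence of `phrase` occur contiguously in `toks`?
contains_phrase <- function(toks, phrase) {
  p <- normalize_tokens(phrase)$surface
  np <- length(p)
  if (np == 0L) return(FALSE)
  n <- length(toks)
  if (n < np) return(FALSE)
  for (i in seq_len(n - np + 1L)) {
    if (all(toks[i:(i + np - 1L)] == p)) return(TRUE)
  }
  FALSE
}

#' Rank documents for a (gene, axis) query
#'
#' Candidates are the documents that mention the gene, fall inside the date
#' window, are not excluded by pmid, keyword or curation history. Each
#' candidate gets three component scores — BM25 over the gene's surface forms
#' plus any boost keywords, concept range, and concept TF-IDF. BM25 and
#' TF-IDF are min-max normalized to `[0, 1]` across the candidate set
#' (constant components map to 0); the range score is `[0, 1]` by
#' construction. The final score is the weighted sum; ties are broken by year
#' descending then pmid descending, so the ranking is total and reproducible.
#'
#' @param query a [triage_query()].
#' @param corpus a corpus tibble.
#' @param lexicon the axis lexicon.
#' @param weights a [score_weights()] object.
#' @param stats optional precomputed [compute_corpus_stats()] (with
#'   `concept_df` from `lexicon`); computed from `corpus` when `NULL`.
#' @param history optional [curation_history()]; pmids already processed under
#'   the same query key are dropped from the candidates.
#' @return a tibble of class `triage_ranking` with columns `rank`, `pmid`,
#'   `year`, `title`, `bm25`, `range_score`, `tfidf`, `bm25_norm`,
#'   `tfidf_norm`, `final_score`, `status`; sorted by `final_score`
#'   descending, truncated to `max_results`.
#' @export
triage <- function(query, corpus, lexicon, weights = score_weights(),
                   stats = NULL, history = NULL) {
  stopifnot(inherits(query, "triage_query"), inherits(weights, "score_weights"))
  if (is.null(stats)) stats <- compute_corpus_stats(corpus, lexicon)

  done <- character()
  if (!is.null(history)) done <- processed_pmids(history, query_key(query))

  keep <- vapply(seq_len(nrow(corpus)), FUN.VALUE = logical(1), function(i) {
    d <- corpus[i, ]
    if (d$pmid %in% query$excluded_pmids || d$pmid %in% done) return(FALSE)
    if (!is.null(query$date_from) &&
        (is.na(d$year) || d$year < query$date_from)) return(FALSE)
    if (!is.null(query$date_to) &&
        (is.na(d$year) || d$year > query$date_to)) return(FALSE)
    if (nrow(find_gene_mentions(d, query$gene)) == 0L) return(FALSE)
    if (length(query$excluded_keywords)) {
      toks <- c(normalize_tokens(d$title)$surface,
                normalize_tokens(d$abstract)$surface)
      for (kw in query$excluded_keywords) {
        if (contains_phrase(toks, kw)) return(FALSE)
      }
    }
    TRUE
  })
  cand <- corpus[keep, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty_triage(query, weights))

  q_terms <- c(query$gene$symbol, query$gene$synonyms, query$boost_keywords)
  distinct_counts <- vapply(seq_len(nrow(cand)), FUN.VALUE = integer(1),
                            function(i) {
    length(distinct_concepts(extract_mentions(cand[i, ], lexicon)))
  })
  max_distinct <- max(distinct_counts)
  res <- tibble(
    pmid = cand$pmid,
    year = cand$year,
    title = cand$title,
    bm25 = vapply(seq_len(nrow(cand)), FUN.VALUE = numeric(1), function(i) {
      bm25_score(q_terms, cand[i, ], stats, k1 = weights$k1, b = weights$b)
    }),
    range_score = if (max_distinct > 0) distinct_counts / max_distinct else
      rep(0, nrow(cand)),
    tfidf = vapply(seq_len(nrow(cand)), FUN.VALUE = numeric(1), function(i) {
      tfidf_doc_score(cand[i, ], lexicon, stats)
    })
  )
  res$bm25_norm <- minmax01(res$bm25)
  res$tfidf_norm <- minmax01(res$tfidf)
  res$final_score <- weights$w_bm25 * res$bm25_norm +
    weights$w_range * res$range_score +
    weights$w_tfidf * res$tfidf_norm
  ord <- order(-res$final_score,
               -ifelse(is.na(res$year), -Inf, res$year),
               -as.numeric(res$pmid))
  res <- res[ord, , drop = FALSE]
  res <- utils::head(res, query$max_results)
  res$rank <- seq_len(nrow(res))
  res$status <- "not_done"
  res <- res[, c("rank", "pmid", "year", "title", "bm25", "range_score",
                 "tfidf", "bm25_norm", "tfidf_norm", "final_score", "status")]
  structure(res,
            class = c("triage_ranking", class(tibble())),
            query_key = query_key(query),
            n_candidates = nrow(cand),
            weights = weights)
}

minmax01 <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) return(rep(0, length(x))) # constant component maps to 0
  (x - rng[1]) / diff(rng)
}

empty_triage <- function(query, weights) {
  structure(
    tibble(
      rank = integer(), pmid = character(), year = integer(),
      title = character(), bm25 = numeric(), range_score = numeric(),
      tfidf = numeric(), bm25_norm = numeric(), tfidf_norm = numeric(),
      final_score = numeric(), status = character()
    ),
    class = c("triage_ranking", class(tibble())),
    query_key = query_key(query), n_candidates = 0L, weights = weights
  )
}

#' @exportS3Method generics::glance
glance.triage_ranking <- function(x, ...) {
  tibble(
    query_key = attr(x, "query_key"),
    n_candidates = attr(x, "n_candidates"),
    n_returned = nrow(x),
    top_score = if (nrow(x)) x$final_score[1] else NA_real_
  )
}

#' Write a triage ranking to TSV
#'
#' @param ranking a `triage_ranking`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_triage_tsv <- function(ranking, path) {
  out <- ranking[, c("rank", "pmid", "year", "title", "bm25", "range_score",
                     "tfidf", "final_score", "status")]
  readr::write_tsv(as_tibble(out), path, progress = FALSE)
  invisible(path)
}
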