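# Independent reference implementations used as oracles. These deliberately
# take different code paths from the package: plain strsplit tokenization,
# direct double loops, no shared helpers beyond base R.

# crude independent tokenizer: lowercase alphanumeric runs
oracle_tokens <- function(text) {
  toks <- strsplit(tolower(text), "[^a-z0-9]+")[[1]]
  toks[nzchar(toks)]
}

# brute-force BM25 over a corpus given as a list of token vectors
oracle_bm25 <- function(query_terms, doc_tokens_list, doc_i, k1, b) {
  q <- unique(unlist(lapply(query_terms, oracle_tokens)))
  N <- length(doc_tokens_list)
  avgdl <- mean(vapply(doc_tokens_list, length, integer(1)))
  d <- doc_tokens_list[[doc_i]]
  total <- 0
  for (t in q) {
    df <- sum(vapply(doc_tokens_list, function(x) t %in% x, logical(1)))
    if (df == 0) next
    ft <- sum(d == t)
    if (ft == 0) next
    idf <- log(1 + (N - df + 0.5) / (df + 0.5))
    total <- total + idf * ft * (k1 + 1) /
      (ft + k1 * (1 - b + b * length(d) / avgdl))
  }
  total
}

# brute-force dictionary matcher: enumerate every token window, compare
# against every lexicon surface form, resolve overlaps longer-span-first then
# leftmost. `forms` is a named list: surface form -> character vector of ids.
oracle_match <- function(text, forms) {
  toks <- strsplit(tolower(text), "[^a-z0-9]+")
  # need offsets: redo with gregexpr on the original
  m <- gregexpr("[A-Za-z0-9]+", text)[[1]]
  if (m[1] == -1) {
    return(data.frame(concept_id = character(), start = integer(),
                      end = integer()))
  }
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  surf <- tolower(substring(text, starts, starts + lens - 1L))
  n <- length(surf)
  form_toks <- lapply(names(forms), oracle_tokens)
  hits <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      win <- surf[i:j]
      for (f in seq_along(form_toks)) {
        if (identical(win, form_toks[[f]])) {
          hits[[length(hits) + 1L]] <- list(
            i = i, j = j, ids = forms[[f]],
            start = starts[i] - 1L, end = starts[j] + lens[j] - 1L
          )
        }
      }
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(concept_id = character(), start = integer(),
                      end = integer()))
  }
  ord <- order(-vapply(hits, function(h) h$j - h$i, integer(1)),
               vapply(hits, function(h) h$i, integer(1)))
  used <- logical(n)
  out <- list()
  for (h in hits[ord]) {
    if (!any(used[h$i:h$j])) {
      used[h$i:h$j] <- TRUE
      out[[length(out) + 1L]] <- data.frame(
        concept_id = h$ids, start = h$start, end = h$end
      )
    }
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$concept_id), , drop = FALSE]
}

# direct precision-at-k scorer over a list pmid -> logical vector in rank
# order
oracle_patk <- function(judged, k) {
  mean(vapply(judged, function(v) sum(head(v, k)) / k, numeric(1)))
}
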