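toy_corpus <- function() {
  fixture_corpus(
    fixture_doc("101", title = "ZAP70 signaling",
                abstract = "ZAP70 binds LAT and drives autophagy", 2005),
    fixture_doc("102", title = "Kinase survey",
                abstract = "Many kinases including ZAP70 and CDK2 act", 2010),
    fixture_doc("103", title = "Unrelated botany",
                abstract = "Leaf growth in maize fields", 2008)
  )
}

test_that("BM25 is zero without query-term overlap and warns when empty", {
  corpus <- toy_corpus()
  st <- compute_corpus_stats(corpus)
  expect_equal(bm25_score("absentterm", corpus[1, ], st), 0)
  expect_warning(s <- bm25_score(character(), corpus[1, ], st), "empty query")
  expect_equal(s, 0)
})

test_that("BM25 approaches presence-weighted idf as k1 -> 0 with b = 0", {
  corpus <- toy_corpus()
  st <- compute_corpus_stats(corpus)
  got <- bm25_score(c("zap70", "autophagy"), corpus[1, ], st,
                    k1 = 1e-6, b = 0)
  idf <- function(t) log(1 + (st$N - st$df[[t]] + 0.5) / (st$df[[t]] + 0.5))
  expect_equal(got, idf("zap70") + idf("autophagy"), tolerance = 1e-4)
})

test_that("BM25 equals an independently coded brute-force implementation", {
  corpus <- toy_corpus()
  st <- compute_corpus_stats(corpus)
  tok_list <- lapply(seq_len(nrow(corpus)), function(i) {
    c(oracle_tokens(corpus$title[i]), oracle_tokens(corpus$abstract[i]))
  })
  for (i in 1:3) {
    expect_equal(
      bm25_score(c("ZAP70", "autophagy"), corpus[i, ], st,
                 k1 = 1.2, b = 0.75),
      oracle_bm25(c("ZAP70", "autophagy"), tok_list, i, k1 = 1.2, b = 0.75)
    )
  }
})

test_that("BM25 matches the oracle on all random corpora <= 4 docs x 6 tokens", {
  withr::with_seed(23, {
    vocab <- c("qa", "qb", "qc", "qd", "qe")
    for (rep in 1:25) {
      n <- sample(1:4, 1)
      docs <- vapply(seq_len(n), FUN.VALUE = character(1), function(i) {
        paste(sample(vocab, sample(1:6, 1), replace = TRUE), collapse = " ")
      })
      corpus <- fixture_corpus(lapply(seq_len(n), function(i) {
        fixture_doc(as.character(i), abstract = docs[i])
      }))
      st <- compute_corpus_stats(corpus)
      tok_list <- lapply(docs, oracle_tokens)
      q <- sample(vocab, 2)
      for (i in seq_len(n)) {
        expect_equal(
          bm25_score(q, corpus[i, ], st, k1 = 1.2, b = 0.75),
          oracle_bm25(q, tok_list, i, k1 = 1.2, b = 0.75),
          info = paste(rep, i)
        )
      }
    }
  })
})

test_that("concept range score normalizes by the richest candidate", {
  lex <- go_cycle_lexicon()
  doc0 <- fixture_doc("1", abstract = "no concepts at all")
  expect_equal(concept_range_score(doc0, lex, 6), 0)
  doc3 <- fixture_doc("2",
                      abstract = "autophagy, apoptosis and cell cycle")
  expect_equal(concept_range_score(doc3, lex, 6), 0.5)
  expect_equal(concept_range_score(doc3, lex, 3), 1.0)
  expect_equal(concept_range_score(doc3, lex, 0), 0)
})

test_that("document TF-IDF follows tf * ln(N/df) with stale-stats guard", {
  lex <- go_cycle_lexicon()
  corpus <- fixture_corpus(
    fixture_doc("1", abstract = "autophagy twice: autophagy"),
    fixture_doc("2", abstract = "autophagy again"),
    fixture_doc("3", abstract = "cell cycle"),
    fixture_doc("4", abstract = "cell cycle and cell cycle")
  )
  st <- compute_corpus_stats(corpus, lex)
  # tf=2, df=2, N=4 -> 2*ln(2)
  expect_equal(tfidf_doc_score(corpus[1, ], lex, st), 2 * log(2))
  expect_equal(tfidf_doc_score(fixture_doc("9", abstract = "plain"), lex, st),
               0)
  # concept present in all docs contributes ln(1) = 0
  all_corpus <- fixture_corpus(
    fixture_doc("1", abstract = "autophagy"),
    fixture_doc("2", abstract = "autophagy")
  )
  st2 <- compute_corpus_stats(all_corpus, lex)
  expect_equal(tfidf_doc_score(all_corpus[1, ], lex, st2), 0)
  # stale stats: concept seen in doc but absent from concept_df
  st3 <- st2
  st3$concept_df <- c("GO:0007049" = 1L)
  expect_error(tfidf_doc_score(all_corpus[1, ], lex, st3), "stale")
})

test_that("triage with pure BM25 weights reduces to BM25 order", {
  lex <- go_cycle_lexicon()
  corpus <- toy_corpus()
  gene <- fixture_gene()
  st <- compute_corpus_stats(corpus, lex)
  q <- triage_query(gene, "BP")
  res <- triage(q, corpus, lex, score_weights(1, 0, 0), stats = st)
  raw <- vapply(which(corpus$pmid %in% res$pmid), FUN.VALUE = numeric(1),
                function(i) bm25_score(gene$symbol, corpus[i, ], st))
  names(raw) <- corpus$pmid[corpus$pmid %in% res$pmid]
  expect_equal(res$pmid, names(sort(raw, decreasing = TRUE)))
})

test_that("filters honor excluded pmids, keywords and the date window", {
  lex <- go_cycle_lexicon()
  corpus <- toy_corpus()
  gene <- fixture_gene()
  base <- triage(triage_query(gene, "BP"), corpus, lex)
  expect_setequal(base$pmid, c("101", "102"))

  res <- triage(triage_query(gene, "BP", excluded_pmids = "101"),
                corpus, lex)
  expect_false("101" %in% res$pmid)

  # an excluded keyword can only shrink the candidate set
  res_kw <- triage(triage_query(gene, "BP", excluded_keywords = "LAT"),
                   corpus, lex)
  expect_true(all(res_kw$pmid %in% base$pmid))
  expect_false("101" %in% res_kw$pmid)

  res_date <- triage(triage_query(gene, "BP", date_from = 2008), corpus, lex)
  expect_equal(res_date$pmid, "102")

  res_max <- triage(triage_query(gene, "BP", max_results = 1), corpus, lex)
  expect_equal(nrow(res_max), 1L)
})

test_that("ranking is a sorted permutation and weight-scale invariant", {
  lex <- go_cycle_lexicon()
  corpus <- toy_corpus()
  gene <- fixture_gene()
  q <- triage_query(gene, "BP")
  r1 <- triage(q, corpus, lex, score_weights(0.2, 0.3, 0.5))
  r2 <- triage(q, corpus, lex, score_weights(2, 3, 5))
  expect_equal(r1$pmid, r2$pmid)
  expect_equal(r1$rank, seq_len(nrow(r1)))
  expect_true(all(diff(r1$final_score) <= 1e-12))
})

test_that("score ties break by year then pmid, deterministically", {
  lex <- go_cycle_lexicon()
  corpus <- fixture_corpus(
    fixture_doc("201", abstract = "ZAP70 acts", year = 2001),
    fixture_doc("202", abstract = "ZAP70 acts", year = 2005),
    fixture_doc("203", abstract = "ZAP70 acts", year = 2005)
  )
  gene <- fixture_gene()
  res <- triage(triage_query(gene, "BP"), corpus, lex)
  # identical scores: newest year first, larger pmid first within a year
  expect_equal(res$pmid, c("203", "202", "201"))
  expect_identical(res$pmid,
                   triage(triage_query(gene, "BP"), corpus, lex)$pmid)
})

test_that("history hides processed pmids per query, not globally", {
  lex <- go_cycle_lexicon()
  corpus <- toy_corpus()
  gene <- fixture_gene()
  q <- triage_query(gene, "BP")
  res <- triage(q, corpus, lex)
  h <- curation_history()
  h <- mark_processed(h, q, res$pmid[1], "completed")
  res2 <- triage(q, corpus, lex, history = h)
  expect_false(res$pmid[1] %in% res2$pmid)

  other_gene <- fixture_gene("CDK2", "NX_P24941")
  q2 <- triage_query(other_gene, "BP")
  res3 <- triage(q2, corpus, lex, history = h)
  expect_true("102" %in% res3$pmid) # same pmid still returned for other gene
})

test_that("history log replays exactly and forbids status regression", {
  gene <- fixture_gene()
  q <- triage_query(gene, "BP")
  h <- curation_history()
  h <- mark_processed(h, q, "101", "partial")
  h <- mark_processed(h, q, "101", "completed")
  h <- mark_processed(h, q, "102", "completed")
  expect_error(mark_processed(h, q, "101", "partial"), "regression")

  path <- withr::local_tempfile(fileext = ".jsonl")
  write_history(h, path)
  replayed <- read_history(path)
  expect_equal(as.data.frame(replayed), as.data.frame(h))
})
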