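test_that("triage agreement reproduces the published BP breakdown", {
  ag <- counts_to_agreement(162, 39, 41)
  expect_equal(ag$total, 242)
  expect_equal(ag$pct_accept, 67L)
  expect_equal(ag$pct_reject, 16L)
  expect_equal(ag$pct_split, 17L)
  expect_equal(ag$agreement_pct, 83L)
})

test_that("triage agreement from decisions is symmetric and validated", {
  pmids <- sprintf("p%02d", 1:10)
  a <- fixture_decisions("A", pmids, c(rep(TRUE, 6), rep(FALSE, 4)))
  b <- fixture_decisions("B", pmids, c(rep(TRUE, 5), rep(FALSE, 5)))
  ab <- triage_agreement(a, b)
  ba <- triage_agreement(b, a)
  expect_equal(ab$agreement_pct, ba$agreement_pct)
  expect_equal(ab$both_accept, 5)
  expect_equal(ab$split, 1)

  expect_equal(triage_agreement(a, a)$agreement_pct, 100L)

  flip <- fixture_decisions("B", pmids[1:4], !a$relevant[1:4])
  ag0 <- triage_agreement(a[1:4, ], flip)
  expect_equal(ag0$agreement_pct, 0L)
  expect_equal(ag0$pct_split, 100L)

  expect_error(triage_agreement(a, b[1:9, ]), "different pmid sets.*p10")
})

test_that("concept precision reproduces both published axis rows", {
  expect_equal(concept_precision(review_counts(699, 413, 2061)), 35L)
  expect_equal(concept_precision(review_counts(1094, 146, 3727)), 25L)
  expect_equal(concept_precision(review_counts(10, 0, 0)), 100L)
  expect_error(concept_precision(review_counts(0, 0, 0)), "undefined")
})

test_that("precision is invariant to permuting the review list", {
  withr::with_seed(5, {
    actions <- sample(c(rep("accepted", 7), rep("modified", 4),
                        rep("rejected", 9)))
    counts <- review_counts(sum(actions == "accepted"),
                            sum(actions == "modified"),
                            sum(actions == "rejected"))
    shuffled <- sample(actions)
    counts2 <- review_counts(sum(shuffled == "accepted"),
                             sum(shuffled == "modified"),
                             sum(shuffled == "rejected"))
    expect_equal(concept_precision(counts), concept_precision(counts2))
  })
})

test_that("class-level recall pools gold classes over abstracts", {
  cm <- tibble::tibble(
    pmid = c("1", "1", "1", "2", "2"),
    concept_id = c("X:1", "X:2", "X:3", "X:4", "X:5"),
    class = c(1L, 1L, 2L, 1L, 2L)
  )
  a <- fixture_decisions("A", c("1", "2"), c(TRUE, TRUE),
                         concepts = list(c("X:1", "X:3"), c("X:4", "X:5")))
  b <- fixture_decisions("B", c("1", "2"), c(TRUE, TRUE),
                         concepts = list(c("X:2", "X:3"), "X:4"))
  # both-mode gold: pmid 1 {1,2}, pmid 2 {1}; X:2 is class 1 so it matches X:1
  sys_all <- tibble::tibble(pmid = c("1", "1", "2"),
                            concept_id = c("X:2", "X:3", "X:4"))
  expect_equal(concept_recall(sys_all, a, b, cm, "both"), 100)

  sys_half <- tibble::tibble(pmid = "1", concept_id = "X:1")
  # hits class 1 of pmid 1 only: 1 of 3 both-gold class occurrences
  expect_equal(concept_recall(sys_half, a, b, cm, "both"), 100 / 3)

  # either-mode has its own, larger denominator (4 class occurrences)
  expect_equal(concept_recall(sys_half, a, b, cm, "either"), 25)

  expect_error(
    concept_recall(tibble::tibble(pmid = "1", concept_id = "X:9"),
                   a, b, cm, "both"),
    "X:9"
  )
})

test_that("concept IAA reproduces the published common-term rates", {
  # 45 abstracts, 42 with a common class -> 93%; 48 of 51 -> 94%
  make_pair <- function(n, n_common) {
    pmids <- sprintf("q%03d", seq_len(n))
    cm <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
      tibble::tibble(pmid = pmids[i],
                     concept_id = c("X:1", "X:2"), class = c(1L, 2L))
    }))
    a <- fixture_decisions("A", pmids, TRUE,
                           concepts = rep(list("X:1"), n))
    b_concepts <- c(rep(list("X:1"), n_common),
                    rep(list("X:2"), n - n_common))
    b <- fixture_decisions("B", pmids, TRUE, concepts = b_concepts)
    iaa_concepts(a, b, cm)
  }
  expect_equal(make_pair(45, 42)$pct_abstracts_with_common_term, 93L)
  expect_equal(make_pair(51, 48)$pct_abstracts_with_common_term, 94L)

  # identical concept sets agree perfectly
  pmids <- c("1", "2")
  cm <- tibble::tibble(pmid = c("1", "2"), concept_id = "X:1", class = 1L)
  a <- fixture_decisions("A", pmids, TRUE, concepts = rep(list("X:1"), 2))
  expect_equal(iaa_concepts(a, a, cm)$mean_agreement_pct, 100)

  # abstracts with an empty union are excluded with a warning
  a2 <- fixture_decisions("A", c("1", "2"), c(TRUE, FALSE),
                          concepts = list("X:1", character()))
  expect_warning(res <- iaa_concepts(a2, a2, cm), "excluded")
  expect_equal(res$n_abstracts, 1L)
})

test_that("precision at rank follows the TREC fixed-k convention", {
  all_top1 <- tibble::tibble(pmid = c("1", "2", "3"), correct = TRUE)
  expect_equal(precision_at_rank(all_top1, 1), 1.0)

  two <- tibble::tibble(
    pmid = rep(c("1", "2"), each = 5),
    correct = c(TRUE, TRUE, TRUE, FALSE, FALSE,
                TRUE, FALSE, FALSE, FALSE, FALSE)
  )
  expect_equal(precision_at_rank(two, 5), 0.4) # (3/5 + 1/5) / 2

  # a pmid with no proposals counts zero with unchanged denominator
  expect_equal(precision_at_rank(all_top1, 1, pmids = c("1", "2", "3", "4")),
               0.75)
  expect_error(precision_at_rank(all_top1, 0), ">= 1")
})

test_that("precision at rank matches a brute-force scorer on random data", {
  withr::with_seed(31, {
    pmids <- sprintf("r%02d", 1:10)
    judged <- lapply(pmids, function(p) runif(sample(3:8, 1)) < 0.5)
    names(judged) <- pmids
    tab <- dplyr::bind_rows(lapply(pmids, function(p) {
      tibble::tibble(pmid = p, correct = judged[[p]])
    }))
    for (k in c(1, 3, 5)) {
      expect_equal(precision_at_rank(tab, k), oracle_patk(judged, k))
    }
    # P@k never leaves [0, 1] and is non-increasing when correctness is a
    # prefix property
    prefix <- lapply(judged, function(v) sort(v, decreasing = TRUE))
    ptab <- dplyr::bind_rows(lapply(pmids, function(p) {
      tibble::tibble(pmid = p, correct = prefix[[p]])
    }))
    vals <- vapply(1:6, function(k) precision_at_rank(ptab, k), numeric(1))
    expect_true(all(vals >= 0 & vals <= 1))
    expect_true(all(diff(vals) <= 1e-12))
  })
})

test_that("relative gain reproduces the published re-ranking improvements", {
  expect_equal(relative_gain(0.48, 0.63), 31L)
  expect_equal(relative_gain(0.28, 0.35), 25L)
  expect_equal(relative_gain(0.48, 0.59), 23L)
  expect_equal(relative_gain(0.37, 0.37), 0L)
  expect_error(relative_gain(0, 0.5), "> 0")
})

test_that("rejection table reproduces the signaling row and flags", {
  reviews <- tibble::tibble(
    concept_id = c(rep("GO:0023052", 273), rep("GO:0009405", 42),
                   rep("GO:0016310", 29)),
    action = c(rep("rejected", 154), rep("modified", 63), rep("accepted", 56),
               rep("rejected", 42),
               rep("rejected", 29))
  )
  tab <- term_rejection_table(reviews, min_total = 30L)
  sig <- tab[tab$concept_id == "GO:0023052", ]
  expect_equal(c(sig$pct_rejected, sig$pct_modified, sig$pct_accepted),
               c(56L, 23L, 21L))
  expect_false(sig$always_rejected)
  # below the proposal threshold: absent
  expect_false("GO:0016310" %in% tab$concept_id)
  # all-rejected concept flagged
  expect_true(tab$always_rejected[tab$concept_id == "GO:0009405"])
  # sorted by rejection count
  expect_equal(tab$concept_id[1], "GO:0023052")
})

test_that("half-up rounding reproduces the printed percentage cells", {
  expect_equal(pct_half_up(699, 3175), 22L)
  expect_equal(pct_half_up(2061, 3175), 65L)
  expect_equal(pct_half_up(162, 242), 67L)
  expect_equal(round_half_up(c(0.5, 1.5, 2.4)), c(1L, 2L, 2L))
})
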