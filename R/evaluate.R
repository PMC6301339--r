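#' Read curator judgment files
#'
#' TSV with columns `curator_id`, `pmid`, `axis`, `relevant` (logical or
#' 0/1), `concept_ids` (semicolon-separated, empty allowed). A decision with
#' `relevant = FALSE` must carry no concepts.
#'
#' @param path path to the TSV file.
#' @return a tibble with columns `curator_id`, `pmid`, `axis`, `relevant`
#'   (logical), `concepts` (list-column of character vectors).
#' @export
read_judgments <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  need <- c("curator_id", "pmid", "axis", "relevant")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    abort(paste0(path, ": missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  rel <- tolower(trimws(tab$relevant)) %in% c("true", "1", "t", "yes")
  concepts <- lapply(seq_len(nrow(tab)), function(i) {
    v <- tab[["concept_ids"]][i]
    if (is.null(v) || is.na(v) || !nzchar(trimws(v))) character()
    else trimws(stringi::stri_split_fixed(v, ";")[[1]])
  })
  bad <- which(!rel & lengths(concepts) > 0L)
  if (length(bad)) {
    abort(sprintf("%s: non-relevant decision with concepts on data line %s",
                  path, paste(bad, collapse = ", ")))
  }
  tibble(curator_id = tab$curator_id, pmid = tab$pmid, axis = tab$axis,
         relevant = rel, concepts = concepts)
}

#' Read a semantic-class map
#'
#' TSV with columns `pmid`, `concept_id`, `class`: the manual per-abstract
#' grouping of near-equivalent concepts that serves as the equivalence unit
#' for agreement and recall (two concepts in the same class count as the same
#' annotation).
#'
#' @param path path to the TSV file.
#' @return a tibble with columns `pmid`, `concept_id`, `class` (integer).
#' @export
read_classmap <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  need <- c("pmid", "concept_id", "class")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    abort(paste0(path, ": missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  tibble(pmid = tab$pmid, concept_id = tab$concept_id,
         class = as.integer(tab$class))
}

# classes of a concept set for one pmid; error on unmapped concepts
classes_of <- function(classmap, pmid, concept_ids) {
  if (length(concept_ids) == 0L) return(integer())
  sub <- classmap[classmap$pmid == pmid, , drop = FALSE]
  cl <- sub$class[match(concept_ids, sub$concept_id)]
  if (anyNA(cl)) {
    abort(paste0("no semantic class for pmid ", pmid, ", concept ",
                 paste(concept_ids[is.na(cl)], collapse = ", ")))
  }
  unique(cl)
}

#' Triage agreement between two curators
#'
#' Counts, over a shared pmid set, how often both curators accepted a paper
#' as relevant for the axis, both rejected it, or split; percentages are
#' integer, rounded half-up, and the overall agreement is the percentage of
#' identical decisions.
#'
#' @param dec_a,dec_b judgment tibbles ([read_judgments()]) covering the same
#'   pmids, one row per pmid each.
#' @return a one-row tibble with columns `both_accept`, `both_reject`,
#'   `split`, `total`, `pct_accept`, `pct_reject`, `pct_split`,
#'   `agreement_pct`.
#' @export
triage_agreement <- function(dec_a, dec_b) {
  if (!setequal(dec_a$pmid, dec_b$pmid)) {
    only_a <- setdiff(dec_a$pmid, dec_b$pmid)
    only_b <- setdiff(dec_b$pmid, dec_a$pmid)
    abort(paste0(
      "curators judged different pmid sets; only in A: ",
      paste(only_a, collapse = ", "), "; only in B: ",
      paste(only_b, collapse = ", ")
    ))
  }
  b <- dec_b$relevant[match(dec_a$pmid, dec_b$pmid)]
  a <- dec_a$relevant
  counts_to_agreement(sum(a & b), sum(!a & !b), sum(a != b))
}

#' Triage agreement from raw counts
#'
#' The same computation as [triage_agreement()] starting from the three
#' printed counts (papers accepted by both, rejected by both, split).
#'
#' @param both_accept,both_reject,split non-negative integer counts.
#' @return a one-row tibble as for [triage_agreement()].
#' @export
counts_to_agreement <- function(both_accept, both_reject, split) {
  total <- both_accept + both_reject + split
  if (total == 0L) abort("no decisions: agreement undefined")
  tibble(
    both_accept = both_accept, both_reject = both_reject, split = split,
    total = total,
    pct_accept = pct_half_up(both_accept, total),
    pct_reject = pct_half_up(both_reject, total),
    pct_split = pct_half_up(split, total),
    agreement_pct = pct_half_up(both_accept + both_reject, total)
  )
}

#' Review counts for a set of proposed descriptors
#'
#' @param accepted,modified,rejected non-negative integer counts of review
#'   outcomes; the total is their sum.
#' @return a one-row tibble of class `review_counts`.
#' @export
review_counts <- function(accepted, modified, rejected) {
  stopifnot(accepted >= 0, modified >= 0, rejected >= 0)
  structure(
    tibble(total = accepted + modified + rejected,
           accepted = accepted, modified = modified, rejected = rejected),
    class = c("review_counts", class(tibble()))
  )
}

#' Concept-extraction precision from review counts
#'
#' The fraction of proposed descriptors the curators approved or modified
#' (a modification still credits the system with a usable proposal), as an
#' integer percent rounded half-up.
#'
#' @param counts a [review_counts()] row, or anything with columns/fields
#'   `total`, `accepted`, `modified`.
#' @return integer percent.
#' @export
concept_precision <- function(counts) {
  total <- counts$total
  if (is.null(total) || total == 0) abort("total = 0: precision undefined")
  pct_half_up(counts$accepted + counts$modified, total)
}

#' Class-level concept recall of system output against curator gold
#'
#' The gold units are semantic classes per abstract: the classes of the
#' concepts chosen by both curators (`mode = "both"`) or by at least one
#' (`mode = "either"`). Recall is the percentage of gold class occurrences
#' (pooled over pmids) for which the system proposed at least one concept of
#' that class. Equivalence is always class-level, never raw-id-level.
#'
#' @param system_concepts a tibble with columns `pmid`, `concept_id`: the
#'   system's proposals.
#' @param dec_a,dec_b curator judgment tibbles.
#' @param classmap a [read_classmap()] tibble covering every referenced
#'   concept.
#' @param mode `"both"` or `"either"`.
#' @return recall as a percentage (real, not rounded).
#' @export
concept_recall <- function(system_concepts, dec_a, dec_b, classmap,
                           mode = c("both", "either")) {
  mode <- match.arg(mode)
  pmids <- union(dec_a$pmid, dec_b$pmid)
  n_gold <- 0L
  n_hit <- 0L
  for (p in pmids) {
    ca <- classes_of(classmap, p,
                     unlist(dec_a$concepts[dec_a$pmid == p], use.names = FALSE))
    cb <- classes_of(classmap, p,
                     unlist(dec_b$concepts[dec_b$pmid == p], use.names = FALSE))
    gold <- if (mode == "both") intersect(ca, cb) else union(ca, cb)
    if (length(gold) == 0L) next
    sys_ids <- system_concepts$concept_id[system_concepts$pmid == p]
    sys_cl <- classes_of(classmap, p, sys_ids)
    n_gold <- n_gold + length(gold)
    n_hit <- n_hit + sum(gold %in% sys_cl)
  }
  if (n_gold == 0L) abort("no gold classes: recall undefined")
  100 * n_hit / n_gold
}

#' Inter-annotator agreement on extracted concepts
#'
#' Per abstract, the two curators' concept sets are mapped to semantic
#' classes; agreement is the proportion of classes found by both relative to
#' all classes found by either. Reports the mean of that proportion over
#' abstracts, the percentage of abstracts with at least one common class
#' (rounded half-up), and the histogram of common-class counts. Abstracts
#' where neither curator found any concept are excluded with a warning.
#'
#' @param dec_a,dec_b curator judgment tibbles.
#' @param classmap a [read_classmap()] tibble.
#' @return a list with `pct_abstracts_with_common_term` (integer percent),
#'   `mean_agreement_pct` (real), `n_abstracts`, and `histogram` (a tibble
#'   `common_classes`, `n`).
#' @export
iaa_concepts <- function(dec_a, dec_b, classmap) {
  pmids <- union(dec_a$pmid, dec_b$pmid)
  common <- integer()
  ratio <- numeric()
  skipped <- character()
  for (p in pmids) {
    ca <- classes_of(classmap, p,
                     unlist(dec_a$concepts[dec_a$pmid == p], use.names = FALSE))
    cb <- classes_of(classmap, p,
                     unlist(dec_b$concepts[dec_b$pmid == p], use.names = FALSE))
    u <- union(ca, cb)
    if (length(u) == 0L) {
      skipped <- c(skipped, p)
      next
    }
    k <- length(intersect(ca, cb))
    common <- c(common, k)
    ratio <- c(ratio, k / length(u))
  }
  if (length(skipped)) {
    warn(paste0("abstracts with no concepts from either curator excluded: ",
                paste(skipped, collapse = ", ")))
  }
  if (length(common) == 0L) abort("no scorable abstracts")
  hist_tab <- table(common)
  list(
    pct_abstracts_with_common_term = pct_half_up(sum(common >= 1L),
                                                 length(common)),
    mean_agreement_pct = mean(100 * ratio),
    n_abstracts = length(common),
    histogram = tibble(common_classes = as.integer(names(hist_tab)),
                       n = as.integer(hist_tab))
  )
}

#' Precision at rank k over ranked judgments
#'
#' `k = 1` is P0, the mean over abstracts of whether the top-ranked proposal
#' was judged correct; for `k > 1` the per-abstract score is the number of
#' correct proposals in the top `k` divided by the fixed denominator `k`
#' (TREC convention), so abstracts with fewer than `k` proposals are
#' penalized, and an abstract with no proposals at all counts 0.
#'
#' @param judgments a tibble with columns `pmid`, `correct` (logical), rows
#'   ordered by the system's proposed rank within each pmid.
#' @param k rank cutoff, `>= 1`.
#' @param pmids optional full evaluation pmid set (defaults to the pmids
#'   present in `judgments`); pmids without rows score 0.
#' @return a real in `[0, 1]`.
#' @export
precision_at_rank <- function(judgments, k, pmids = NULL) {
  if (k < 1L) abort("`k` must be >= 1")
  if (is.null(pmids)) pmids <- unique(judgments$pmid)
  if (length(pmids) == 0L) abort("no abstracts to score")
  per <- vapply(pmids, FUN.VALUE = numeric(1), USE.NAMES = FALSE,
                function(p) {
    corr <- judgments$correct[judgments$pmid == p]
    sum(utils::head(corr, k)) / k
  })
  mean(per)
}

#' Relative gain of an improved metric over a baseline
#'
#' `100 * (improved - baseline) / baseline`, as a signed integer percent
#' rounded half-up.
#'
#' @param baseline,improved metric values; `baseline` must be positive.
#' @return signed integer percent.
#' @export
relative_gain <- function(baseline, improved) {
  if (baseline <= 0) abort("`baseline` must be > 0")
  round_half_up(100 * (improved - baseline) / baseline)
}

#' Per-term rejection table
#'
#' Aggregates review actions per proposed concept: counts and integer
#' percentages of rejected / modified / accepted, sorted by rejected count
#' descending, limited to concepts proposed at least `min_total` times.
#' Concepts rejected every single time are flagged `always_rejected` — the
#' natural candidates for the blacklist.
#'
#' @param reviews a tibble with columns `concept_id`, `action` (each action
#'   one of `"accepted"`, `"modified"`, `"rejected"`).
#' @param lexicon optional lexicon used to attach preferred labels.
#' @param min_total minimum number of proposals for a concept to be listed
#'   (default 30).
#' @return a tibble with columns `concept_id` (+ `label` if a lexicon is
#'   given), `rejected`, `modified`, `accepted`, `total`, `pct_rejected`,
#'   `pct_modified`, `pct_accepted`, `always_rejected`.
#' @export
term_rejection_table <- function(reviews, lexicon = NULL, min_total = 30L) {
  bad <- setdiff(unique(reviews$action),
                 c("accepted", "modified", "rejected"))
  if (length(bad)) {
    abort(paste0("unknown review action(s): ", paste(bad, collapse = ", ")))
  }
  tab <- reviews |>
    group_by(.data$concept_id) |>
    summarise(
      rejected = sum(.data$action == "rejected"),
      modified = sum(.data$action == "modified"),
      accepted = sum(.data$action == "accepted"),
      .groups = "drop"
    ) |>
    mutate(
      total = .data$rejected + .data$modified + .data$accepted,
      pct_rejected = pct_half_up(.data$rejected, .data$total),
      pct_modified = pct_half_up(.data$modified, .data$total),
      pct_accepted = pct_half_up(.data$accepted, .data$total),
      always_rejected = .data$rejected == .data$total
    ) |>
    filter(.data$total >= min_total) |>
    arrange(desc(.data$rejected))
  if (!is.null(lexicon)) {
    lab <- setNames(lexicon$concepts$preferred_label, lexicon$concepts$id)
    tab <- mutate(tab, label = unname(lab[.data$concept_id]),
                  .after = "concept_id")
  }
  tab
}
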