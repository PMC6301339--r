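#' Default relation and evidence code per axis
#'
#' Annotation triplets carry an editable relation and ECO evidence code;
#' the interface-level defaults used when a candidate is generated.
#'
#' @param axis `"BP"` or `"D"`.
#' @return a single string.
#' @export
default_relation <- function(axis) {
  assert_axis(axis)
  if (axis == "BP") "is involved in" else "is associated with"
}

#' @rdname default_relation
#' @export
default_eco <- function(axis) {
  assert_axis(axis)
  "ECO:0000305"
}

#' Generate annotation-triplet candidates for one document
#'
#' A candidate is a curation triplet: subject protein, relation, concept
#' object, evidence code, plus provenance (pmid, sentence, offsets of the
#' concept's first mention). One candidate is produced per distinct non-gene
#' concept; documents without a gene mention yield none. The initial order is
#' the position of each concept's first mention in the text (title before
#' abstract) — the "linear view".
#'
#' @param doc a one-row corpus tibble.
#' @param mentions concept mentions of `doc` from [extract_mentions()].
#' @param gene_mentions gene mentions of `doc` from [find_gene_mentions()].
#' @param subject protein accession used as triplet subject (e.g.
#'   `"NX_P43403"`).
#' @param axis `"BP"` or `"D"` (sets the default relation).
#' @param relation,eco override the axis defaults.
#' @return a tibble of class `annotation_candidates` with columns `subject`,
#'   `relation`, `object_id`, `eco`, `pmid`, `section`, `sentence_index`,
#'   `start`, `end`, `rank_score`, `status`, `modified_object_id`.
#' @export
generate_candidates <- function(doc, mentions, gene_mentions, subject,
                                axis = "BP",
                                relation = default_relation(axis),
                                eco = default_eco(axis)) {
  assert_axis(axis)
  if (nrow(gene_mentions) == 0L) return(empty_candidates())
  m <- mentions[!mentions$concept_id %in% unique(gene_mentions$concept_id), ,
                drop = FALSE]
  if (nrow(m) == 0L) return(empty_candidates())
  ord <- order(match(m$section, c("title", "abstract")), m$start)
  m <- m[ord, , drop = FALSE]
  first <- m[!duplicated(m$concept_id), , drop = FALSE]
  structure(
    tibble(
      subject = subject,
      relation = relation,
      object_id = first$concept_id,
      eco = eco,
      pmid = first$pmid,
      section = first$section,
      sentence_index = first$sentence_index,
      start = first$start,
      end = first$end,
      rank_score = NA_real_,
      status = "pending",
      modified_object_id = NA_character_
    ),
    class = c("annotation_candidates", class(tibble()))
  )
}

empty_candidates <- function() {
  structure(
    tibble(
      subject = character(), relation = character(), object_id = character(),
      eco = character(), pmid = character(), section = character(),
      sentence_index = integer(), start = integer(), end = integer(),
      rank_score = numeric(), status = character(),
      modified_object_id = character()
    ),
    class = c("annotation_candidates", class(tibble()))
  )
}

as_candidates <- function(x) {
  structure(x, class = c("annotation_candidates", class(tibble())))
}

#' Remove blacklisted concepts from a candidate list
#'
#' Candidates whose object concept is on the lexicon blacklist are dropped;
#' the number removed is reported and stored in attribute `"n_removed"`.
#'
#' @param candidates an `annotation_candidates` tibble.
#' @param lexicon a lexicon with its blacklist loaded.
#' @return the surviving candidates.
#' @export
apply_blacklist <- function(candidates, lexicon) {
  stopifnot(inherits(lexicon, "lexicon"))
  drop <- candidates$object_id %in% lexicon$blacklist
  if (any(drop)) {
    cli::cli_inform("removed {sum(drop)} blacklisted candidate{?s}")
  }
  out <- as_candidates(candidates[!drop, , drop = FALSE])
  attr(out, "n_removed") <- sum(drop)
  out
}

#' Re-rank candidates by concept TF-IDF importance
#'
#' Estimates how important each proposed concept is for the current query:
#' `rank_score(c) = tf(c) * ln((background_N + 1) / (background_df(c) + 1))`,
#' where `tf(c)` counts the retrieved documents mentioning `c` (important
#' concepts recur across the retrieved abstracts) and the background document
#' frequency plays the role of a large MEDLINE sample, down-weighting
#' concepts that are effectively regular English words. Candidates are sorted
#' by `rank_score` descending; ties keep text-position order. This is the
#' "ranked view"; the unranked text order is the "linear view".
#'
#' @param candidates an `annotation_candidates` tibble.
#' @param doc_concepts a tibble with columns `pmid`, `concept_id`: the
#'   distinct concepts of each retrieved document for the current query (see
#'   [corpus_concepts()]).
#' @param background_df a tibble with columns `concept_id`, `df`, or a named
#'   numeric vector: concept document frequencies in a large background
#'   corpus.
#' @param background_N size of the background corpus.
#' @return the candidates with `rank_score` filled, sorted by it.
#' @export
tfidf_rank <- function(candidates, doc_concepts, background_df, background_N) {
  if (nrow(candidates) == 0L) return(candidates)
  if (is.data.frame(background_df)) {
    background_df <- setNames(as.numeric(background_df$df),
                              background_df$concept_id)
  }
  dc <- distinct(doc_concepts[, c("pmid", "concept_id")])
  tf_tab <- table(dc$concept_id)
  missing <- setdiff(unique(candidates$object_id), names(background_df))
  if (length(missing)) {
    warn(paste0("concept(s) missing from background frequencies (df = 0 ",
                "assumed): ", paste(missing, collapse = ", ")))
  }
  tf <- vapply(candidates$object_id, FUN.VALUE = numeric(1),
               USE.NAMES = FALSE, function(cid) {
    if (cid %in% names(tf_tab)) as.numeric(tf_tab[[cid]]) else 0
  })
  df <- vapply(candidates$object_id, FUN.VALUE = numeric(1),
               USE.NAMES = FALSE, function(cid) {
    if (cid %in% names(background_df)) background_df[[cid]] else 0
  })
  score <- tf * log((background_N + 1) / (df + 1))
  out <- candidates
  out$rank_score <- score
  as_candidates(out[order_desc_stable(score), , drop = FALSE])
}

#' Distinct concepts per document over a corpus
#'
#' Convenience feeder for [tfidf_rank()]: the distinct (pmid, concept) pairs
#' the matcher finds in each document of a (retrieved) corpus.
#'
#' @param corpus a corpus tibble (typically the triage results joined back to
#'   their documents).
#' @param lexicon the axis lexicon.
#' @return a tibble with columns `pmid`, `concept_id`.
#' @export
corpus_concepts <- function(corpus, lexicon) {
  rows <- purrr::map(seq_len(nrow(corpus)), function(i) {
    ids <- distinct_concepts(extract_mentions(corpus[i, ], lexicon))
    if (length(ids) == 0L) return(NULL)
    tibble(pmid = corpus$pmid[i], concept_id = ids)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0L) tibble(pmid = character(), concept_id = character())
  else out
}

#' Review one annotation candidate
#'
#' Implements the curator review semantics: editing the relation or the
#' evidence code does not change the action type — if the concept is
#' unchanged the candidate is `accepted`; `modify` replaces the concept and
#' requires the new concept to lie in the same ontology branch as the
#' proposal (shared non-root is_a ancestor); `reject` leaves the concept in
#' place and marks it rejected.
#'
#' @param candidate a one-row `annotation_candidates` tibble with status
#'   `"pending"`.
#' @param action `"accept"`, `"modify"` or `"reject"`.
#' @param new_object replacement concept id (required for `"modify"`).
#' @param new_relation,new_eco optional edits applied for any action.
#' @param lexicon the axis lexicon (required for the branch check on
#'   `"modify"`).
#' @return the updated one-row candidate tibble.
#' @export
review <- function(candidate, action, new_object = NULL,
                   new_relation = NULL, new_eco = NULL, lexicon = NULL) {
  stopifnot(is.data.frame(candidate), nrow(candidate) == 1L)
  if (!identical(candidate$status, "pending")) {
    abort(paste0("candidate already reviewed (status ", candidate$status, ")"))
  }
  if (!action %in% c("accept", "modify", "reject")) {
    abort(paste0("unknown review action \"", action, "\""))
  }
  out <- candidate
  if (!is.null(new_relation)) out$relation <- new_relation
  if (!is.null(new_eco)) out$eco <- new_eco
  if (action == "accept") {
    out$status <- "accepted"
  } else if (action == "reject") {
    out$status <- "rejected"
  } else {
    if (is.null(new_object)) abort("modify requires `new_object`")
    if (identical(new_object, candidate$object_id)) {
      abort("modify with an unchanged concept is an accept")
    }
    if (is.null(lexicon)) abort("modify requires `lexicon` for the branch check")
    if (!same_branch(lexicon, candidate$object_id, new_object)) {
      abort(sprintf(
        "%s is not in the same ontology branch as %s: not a valid modification",
        new_object, candidate$object_id
      ))
    }
    out$status <- "modified"
    out$modified_object_id <- new_object
  }
  as_candidates(out)
}

#' Write annotation candidates to TSV
#'
#' @param candidates an `annotation_candidates` tibble.
#' @param path output path.
#' @param lexicon optional lexicon used to add an `object_label` column.
#' @return `path`, invisibly.
#' @export
write_candidates_tsv <- function(candidates, path, lexicon = NULL) {
  out <- as_tibble(candidates)
  if (!is.null(lexicon)) {
    lab <- setNames(lexicon$concepts$preferred_label, lexicon$concepts$id)
    out$object_label <- unname(lab[out$object_id])
    out <- out[, c("subject", "relation", "object_id", "object_label", "eco",
                   "pmid", "sentence_index", "start", "end", "rank_score",
                   "status")]
  } else {
    out <- out[, c("subject", "relation", "object_id", "eco", "pmid",
                   "sentence_index", "start", "end", "rank_score", "status")]
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
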