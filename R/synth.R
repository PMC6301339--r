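#' Configuration for the synthetic study generator
#'
#' The generator emulates the study design every other module is tested
#' against: a mini-ontology per axis, an abstract corpus in which relevant
#' documents carry a gene mention plus several planted concept surface forms
#' while decoys carry filler (or the gene alone), and two simulated curators
#' whose triage decisions are coupled to a target agreement rate.
#'
#' @param seed integer seed; a fixed seed makes every generated artifact
#'   byte-identical across runs.
#' @param n_relevant,n_decoy number of relevant and decoy abstracts
#'   (defaults 20 relevant / 80 decoys, the scale of one per-gene triage
#'   batch).
#' @param concepts_per_doc mean number of planted concepts per relevant
#'   document (each document gets `1 + rpois(mean - 1)`).
#' @param synonym_use_prob probability a planted concept appears as a synonym
#'   rather than its preferred label.
#' @param curator_accept_prob probability a truly relevant document enters
#'   the shared latent "accept" pool both simulated curators perceive.
#' @param curator_concept_recall probability a curator reports each gold
#'   concept of a document they accepted.
#' @param curator_agreement target expected triage agreement between the two
#'   curators (must be `>= 0.5`; decisions are the shared latent decision
#'   flipped independently with probability `e = (1 - sqrt(2a - 1)) / 2`, so
#'   `P(agree) = (1-e)^2 + e^2 = a`).
#' @param vocabulary_size concepts per axis vocabulary (minimum 3).
#' @param zipf_exponent exponent of the Zipf law governing which concepts get
#'   planted (rank-r concept drawn with probability proportional to
#'   `r^-zipf_exponent`).
#' @param n_vague number of deliberately vague single-word concepts (high
#'   background frequency; blacklist material).
#' @param class_merge_frac fraction of adjacent gold concepts sharing a
#'   semantic class, to exercise class-level (not id-level) equivalence.
#' @param background_N size of the simulated background corpus for
#'   [make_background_df()].
#' @param year_range two-element integer vector of publication years.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(seed = 42L, n_relevant = 20L, n_decoy = 80L,
                         concepts_per_doc = 3, synonym_use_prob = 0.3,
                         curator_accept_prob = 0.9,
                         curator_concept_recall = 0.8,
                         curator_agreement = 0.8,
                         vocabulary_size = 40L, zipf_exponent = 1.1,
                         n_vague = 4L, class_merge_frac = 0.2,
                         background_N = 10000L,
                         year_range = c(2000L, 2020L)) {
  probs <- c(synonym_use_prob, curator_accept_prob, curator_concept_recall,
             curator_agreement, class_merge_frac)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (curator_agreement < 0.5) {
    abort("`curator_agreement` must be >= 0.5 for the flip-noise coupling")
  }
  if (vocabulary_size < 3L) abort("`vocabulary_size` must be >= 3")
  structure(
    list(seed = as.integer(seed), n_relevant = as.integer(n_relevant),
         n_decoy = as.integer(n_decoy), concepts_per_doc = concepts_per_doc,
         synonym_use_prob = synonym_use_prob,
         curator_accept_prob = curator_accept_prob,
         curator_concept_recall = curator_concept_recall,
         curator_agreement = curator_agreement,
         vocabulary_size = as.integer(vocabulary_size),
         zipf_exponent = zipf_exponent, n_vague = as.integer(n_vague),
         class_merge_frac = class_merge_frac,
         background_N = as.integer(background_N),
         year_range = as.integer(year_range)),
    class = "synth_config"
  )
}

# word pools; kept disjoint from the filler pool so decoy text never matches
# a concept surface form by accident
.bp_adjectives <- c(
  "alpha", "beta", "gamma", "delta", "kinase", "membrane", "chromatin",
  "mitotic", "lipid", "vesicle", "ribosome", "nuclear", "cytokine",
  "receptor", "histone", "telomere", "axon", "dendrite", "calcium", "proton"
)
.bp_nouns <- c(
  "transport", "assembly", "repair", "fusion", "budding", "elongation",
  "splicing", "folding", "secretion", "adhesion", "migration",
  "polarization", "remodeling", "biogenesis", "maturation", "clearance",
  "turnover", "docking", "priming", "activation"
)
.bp_vague <- c("signaling", "regulation", "growth", "pathogenesis",
               "localization", "formation")
.d_names <- c(
  "barnett", "kestrel", "orwell", "tamsin", "velda", "quimby", "rutland",
  "selkirk", "norwood", "ashby", "calder", "dunmore", "eldric", "farrow",
  "gisela", "halstead", "ivoria", "jarrell", "lenmore", "mirabel"
)
.d_types <- c("syndrome", "carcinoma", "dystrophy", "anemia", "fibrosis",
              "myopathy", "neuropathy", "lymphoma")
.d_vague <- c("tumor", "mutation", "condition", "outcome", "lesion",
              "abnormality")
.filler_words <- c(
  "the", "study", "we", "observed", "results", "samples", "cohort",
  "analysis", "measured", "using", "robust", "values", "data",
  "experiments", "showed", "levels", "increase", "compared", "control",
  "patients", "after", "treatment", "report", "findings", "consistent",
  "suggest", "further", "work", "followup", "baseline"
)

#' Built-in synthetic gene lexicon
#'
#' Three human gene entries (accession, symbol, one synonym each) used as
#' triage query subjects in the generated corpora.
#'
#' @return a gene lexicon tibble as from [read_gene_lexicon()].
#' @export
synth_genes <- function() {
  tibble(
    accession = c("NX_P43403", "NX_Q9NWZ3", "NX_P24941"),
    symbol = c("ZAP70", "IRAK4", "CDK2"),
    synonyms = list("zeta chain associated kinase",
                    "interleukin receptor kinase four",
                    "cyclin dependent kinase two")
  )
}

#' Generate a mini-ontology (OBO) and matching disease terminology (TSV)
#'
#' Builds, deterministically under the config seed, a rooted is_a tree of
#' `vocabulary_size` concepts per axis with multi-word labels, synonyms
#' including a hyphen variant and one deliberately ambiguous synonym shared
#' between two concepts, plus `n_vague` single-word vague concepts of the
#' kind curators reject essentially always (blacklist material). The disease
#' terminology includes an en-dash label whose synonym uses a plain hyphen.
#'
#' @param config a [synth_config()].
#' @return a list with `obo_text` (single string, `"BP"` ontology),
#'   `disease_tsv` (single string, `"D"` terminology), `vague_bp_ids`,
#'   `vague_d_ids` (character vectors).
#' @export
make_mini_ontology <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(config$seed, {
    n <- config$vocabulary_size
    nv <- min(config$n_vague, length(.bp_vague), n - 2L)

    ## --- BP axis (OBO) ---
    ids <- sprintf("SBP:%07d", seq_len(n))
    labels <- character(n)
    labels[1] <- "biological process"
    labels[2:(1 + nv)] <- .bp_vague[seq_len(nv)]
    combos <- expand.grid(a = .bp_adjectives, b = .bp_nouns,
                          stringsAsFactors = FALSE)
    combos <- combos[sample.int(nrow(combos)), ]
    need <- n - 1L - nv
    labels[(2L + nv):n] <- paste(combos$a[seq_len(need)],
                                 combos$b[seq_len(need)])
    parents <- c(NA_character_, rep("", n - 1L))
    for (i in 2:n) parents[i] <- ids[sample.int(i - 1L, 1L)]
    synonyms <- vector("list", n)
    for (i in seq_len(n)) {
      syns <- character()
      words <- strsplit(labels[i], " ", fixed = TRUE)[[1]]
      if (length(words) >= 2L && runif(1) < 0.6) {
        # hyphen variant: "t-cell activation" style
        syns <- c(syns, paste0(words[1], "-",
                               paste(words[-1], collapse = " ")))
      }
      if (length(words) >= 2L && runif(1) < 0.4) {
        syns <- c(syns, paste(rev(words), collapse = " dependent "))
      }
      synonyms[[i]] <- syns
    }
    # one deliberately ambiguous synonym shared between the last two concepts
    synonyms[[n - 1L]] <- c(synonyms[[n - 1L]], "shared pathway term")
    synonyms[[n]] <- c(synonyms[[n]], "shared pathway term")
    obo_text <- paste(c(
      "format-version: 1.2",
      "ontology: synthetic-bp",
      unlist(lapply(seq_len(n), function(i) {
        c("",
          "[Term]",
          paste0("id: ", ids[i]),
          paste0("name: ", labels[i]),
          vapply(synonyms[[i]], FUN.VALUE = character(1), function(s) {
            paste0("synonym: \"", s, "\" EXACT []")
          }),
          if (!is.na(parents[i])) paste0("is_a: ", parents[i], " ! parent"))
      }))
    ), collapse = "\n")

    ## --- D axis (TSV) ---
    d_ids <- sprintf("SD:%05d", seq_len(n))
    d_labels <- character(n)
    d_labels[1] <- "disease"
    nvd <- min(config$n_vague, length(.d_vague), n - 2L)
    d_labels[2:(1 + nvd)] <- .d_vague[seq_len(nvd)]
    d_combos <- expand.grid(a = .d_names, b = .d_types,
                            stringsAsFactors = FALSE)
    d_combos <- d_combos[sample.int(nrow(d_combos)), ]
    need_d <- n - 1L - nvd
    d_labels[(2L + nvd):n] <- paste(d_combos$a[seq_len(need_d)],
                                    d_combos$b[seq_len(need_d)])
    # en-dash double-name label with plain-hyphen synonym
    d_labels[n] <- paste0(.d_names[1], "–", .d_names[2], " syndrome")
    d_syn <- vector("list", n)
    d_syn[[n]] <- paste0(.d_names[1], "-", .d_names[2], " syndrome")
    for (i in 2:(n - 1L)) {
      if (runif(1) < 0.5) {
        w <- strsplit(d_labels[i], " ", fixed = TRUE)[[1]]
        d_syn[[i]] <- paste(rev(w), collapse = " type ")
      } else {
        d_syn[[i]] <- character()
      }
    }
    d_syn[[2]] <- c(d_syn[[2]], "shared disease term")
    d_syn[[3]] <- c(d_syn[[3]], "shared disease term")
    d_parents <- c(NA_character_, vapply(2:n, FUN.VALUE = character(1),
                                         function(i) {
      d_ids[sample.int(i - 1L, 1L)]
    }))
    d_lines <- c(
      "id\tpreferred_label\tsynonyms\tparent_ids",
      vapply(seq_len(n), FUN.VALUE = character(1), function(i) {
        paste(d_ids[i], d_labels[i],
              paste(d_syn[[i]], collapse = "|"),
              if (is.na(d_parents[i])) "" else d_parents[i],
              sep = "\t")
      })
    )
    list(
      obo_text = obo_text,
      disease_tsv = paste(d_lines, collapse = "\n"),
      vague_bp_ids = ids[2:(1 + nv)],
      vague_d_ids = d_ids[2:(1 + nvd)]
    )
  })
}

# zipf sampling weights over concept ranks
zipf_weights <- function(n, s) {
  w <- (seq_len(n))^(-s)
  w / sum(w)
}

sentence_case <- function(words) {
  s <- paste(words, collapse = " ")
  stringi::stri_sub(s, 1, 1) <- toupper(stringi::stri_sub(s, 1, 1))
  paste0(s, ".")
}

#' Generate a synthetic abstract corpus with planted signal
#'
#' Relevant documents embed the query gene's symbol and `k` planted concept
#' surface forms (preferred label with probability `1 - synonym_use_prob`,
#' else a synonym) in filler sentences; concept choice follows a Zipf law
#' over the vocabulary. Decoys embed filler only or the gene alone (half
#' each). The gold table lists every planted (pmid, concept) pair; because
#' surface forms are inserted verbatim, the dictionary matcher recovers the
#' gold with recall 1 by construction.
#'
#' @param config a [synth_config()].
#' @param lexicon the axis lexicon the concepts are planted from.
#' @param gene a gene entry (list with `accession`, `symbol`, `synonyms`).
#' @return a list with `corpus` (tibble as [read_corpus_jsonl()]) and `gold`
#'   (tibble `pmid`, `concept_id`).
#' @export
make_corpus <- function(config, lexicon, gene) {
  stopifnot(inherits(config, "synth_config"), inherits(lexicon, "lexicon"))
  withr::with_seed(config$seed + 1L, {
    cc <- lexicon$concepts[!lexicon$concepts$obsolete, , drop = FALSE]
    cc <- cc[lengths(cc$parent_ids) > 0L, , drop = FALSE] # exclude the root
    w <- zipf_weights(nrow(cc), config$zipf_exponent)
    n_total <- config$n_relevant + config$n_decoy
    pmids <- sprintf("9%06d", seq_len(n_total))
    years <- sample(seq(config$year_range[1], config$year_range[2]),
                    n_total, replace = TRUE)
    filler_sentence <- function(n_words = sample(6:10, 1L)) {
      sample(.filler_words, n_words, replace = TRUE)
    }
    pick_surface <- function(i) {
      syns <- cc$synonyms[[i]]
      if (length(syns) && runif(1) < config$synonym_use_prob) {
        sample(syns, 1L)
      } else {
        cc$preferred_label[i]
      }
    }
    docs <- vector("list", n_total)
    gold <- vector("list", n_total)
    for (d in seq_len(n_total)) {
      relevant <- d <= config$n_relevant
      gene_only <- !relevant && (d - config$n_relevant) %% 2L == 1L
      title <- sentence_case(filler_sentence(5L))
      sentences <- character()
      if (relevant || gene_only) {
        sentences <- c(sentences, sentence_case(
          c(filler_sentence(4L), gene$symbol, filler_sentence(3L))
        ))
      }
      if (relevant) {
        k <- 1L + rpois(1L, max(config$concepts_per_doc - 1, 0))
        k <- min(k, nrow(cc))
        picks <- sample.int(nrow(cc), k, prob = w)
        for (i in picks) {
          sentences <- c(sentences, sentence_case(
            c(filler_sentence(3L), pick_surface(i), filler_sentence(3L))
          ))
        }
        gold[[d]] <- tibble(pmid = pmids[d], concept_id = cc$id[picks])
      }
      sentences <- c(sentences, sentence_case(filler_sentence()))
      docs[[d]] <- tibble(
        pmid = pmids[d], title = title,
        abstract = paste(sentences, collapse = " "),
        year = as.integer(years[d]), journal = "Synthetic J Biocuration"
      )
    }
    list(corpus = bind_rows(docs), gold = bind_rows(gold))
  })
}

#' Simulate two coupled curators over a synthetic corpus
#'
#' Each document's true relevance is whether it has gold concepts. A shared
#' latent decision accepts a truly relevant document with probability
#' `curator_accept_prob`; each curator independently flips that latent
#' decision with probability `e = (1 - sqrt(2a - 1)) / 2`, so the expected
#' triage agreement equals `a = curator_agreement` in closed form. A curator
#' who accepts a document reports each of its gold concepts with probability
#' `curator_concept_recall`. The semantic-class map assigns gold concepts
#' their own class per abstract, except that a `class_merge_frac` fraction of
#' adjacent concepts share a class (exercising class-level equivalence).
#'
#' @param config a [synth_config()].
#' @param gold the gold tibble from [make_corpus()].
#' @param corpus the corpus tibble from [make_corpus()].
#' @param extra_concepts optional tibble (`pmid`, `concept_id`) of additional
#'   concepts (e.g. system output) that must receive semantic classes.
#' @return a list with `curator_a`, `curator_b` (judgment tibbles as
#'   [read_judgments()]) and `classmap` (tibble as [read_classmap()]).
#' @export
simulate_curators <- function(config, gold, corpus, extra_concepts = NULL) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(config$seed + 2L, {
    a <- config$curator_agreement
    e <- (1 - sqrt(2 * a - 1)) / 2
    truth <- corpus$pmid %in% gold$pmid
    latent <- truth & (runif(nrow(corpus)) < config$curator_accept_prob)
    flip_a <- runif(nrow(corpus)) < e
    flip_b <- runif(nrow(corpus)) < e
    dec_a_rel <- xor(latent, flip_a)
    dec_b_rel <- xor(latent, flip_b)
    report <- function(p, accepted) {
      if (!accepted) return(character())
      g <- gold$concept_id[gold$pmid == p]
      g[runif(length(g)) < config$curator_concept_recall]
    }
    dec_a <- tibble(
      curator_id = "A", pmid = corpus$pmid, axis = "BP",
      relevant = dec_a_rel,
      concepts = lapply(seq_len(nrow(corpus)), function(i) {
        report(corpus$pmid[i], dec_a_rel[i])
      })
    )
    dec_b <- tibble(
      curator_id = "B", pmid = corpus$pmid, axis = "BP",
      relevant = dec_b_rel,
      concepts = lapply(seq_len(nrow(corpus)), function(i) {
        report(corpus$pmid[i], dec_b_rel[i])
      })
    )
    all_concepts <- gold
    if (!is.null(extra_concepts)) {
      all_concepts <- distinct(bind_rows(
        gold, extra_concepts[, c("pmid", "concept_id")]
      ))
    }
    classmap <- all_concepts |>
      group_by(.data$pmid) |>
      mutate(class = assign_classes(dplyr::n(), config$class_merge_frac)) |>
      ungroup()
    list(curator_a = dec_a, curator_b = dec_b, classmap = classmap)
  })
}

# class labels 1..m for k concepts, with roughly `frac` of adjacent pairs
# sharing a class
assign_classes <- function(k, frac) {
  if (k == 0L) return(integer())
  cls <- integer(k)
  cls[1] <- 1L
  if (k > 1L) {
    for (i in 2:k) {
      cls[i] <- if (runif(1) < frac) cls[i - 1L] else max(cls[1:(i - 1L)]) + 1L
    }
  }
  cls
}

#' Simulated background concept frequencies
#'
#' Assigns each lexicon concept a document frequency in a simulated
#' background corpus of `background_N` documents: vague concepts get
#' `df = background_N` (zero idf, so the TF-IDF re-ranker demotes them below
#' any specific concept), specific concepts get small frequencies.
#' Deterministic under the config seed.
#'
#' @param config a [synth_config()].
#' @param lexicon the axis lexicon.
#' @param vague_ids concept ids to treat as vague (see
#'   [make_mini_ontology()]).
#' @return a list with `background_df` (tibble `concept_id`, `df`) and `N`.
#' @export
make_background_df <- function(config, lexicon, vague_ids = character()) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(config$seed + 3L, {
    ids <- lexicon$concepts$id
    df <- sample.int(max(config$background_N %/% 100L, 2L),
                     length(ids), replace = TRUE)
    df[ids %in% vague_ids] <- config$background_N
    list(background_df = tibble(concept_id = ids, df = as.integer(df)),
         N = config$background_N)
  })
}

#' Write judgment tibbles to TSV
#'
#' @param decisions a judgment tibble ([read_judgments()] layout).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_judgments <- function(decisions, path) {
  out <- tibble(
    curator_id = decisions$curator_id,
    pmid = decisions$pmid,
    axis = decisions$axis,
    relevant = tolower(as.character(decisions$relevant)),
    concept_ids = vapply(decisions$concepts, FUN.VALUE = character(1),
                         paste, collapse = ";")
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write a corpus tibble as JSONL
#'
#' @param corpus a corpus tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(corpus))) {
    rec <- list(pmid = corpus$pmid[i], title = corpus$title[i],
                abstract = corpus$abstract[i])
    if (!is.na(corpus$year[i])) rec$year <- corpus$year[i]
    if (!is.na(corpus$journal[i])) rec$journal <- corpus$journal[i]
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  }
  invisible(path)
}
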