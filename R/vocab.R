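#' Lexicon: an axis-specific concept vocabulary with a surface-form index
#'
#' A lexicon bundles the concepts of one annotation axis (GO biological
#' process, `"BP"`, or disease terminology, `"D"`) with the normalized
#' surface-form index used by the dictionary matcher and an optional blacklist
#' of concept ids that curators reject essentially always.
#'
#' @param concepts a tibble with columns `id`, `preferred_label`, `synonyms`
#'   (list-column of character vectors), `parent_ids` (list-column), `obsolete`
#'   (logical).
#' @param axis `"BP"` or `"D"`.
#' @return an object of class `lexicon`: a list with elements `axis`,
#'   `concepts`, `surface_index` (named list mapping normalized token-sequence
#'   keys to character vectors of concept ids), `max_key_tokens`, and
#'   `blacklist` (character vector of concept ids).
#' @export
new_lexicon <- function(concepts, axis) {
  assert_axis(axis)
  stopifnot(is.data.frame(concepts))
  need <- c("id", "preferred_label", "synonyms", "parent_ids", "obsolete")
  missing_cols <- setdiff(need, names(concepts))
  if (length(missing_cols)) {
    abort(paste0("concepts table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (any(!nzchar(concepts$id))) abort("concept ids must be non-empty")
  dup <- concepts$id[duplicated(concepts$id)]
  if (length(dup)) {
    abort(paste0("duplicate concept id(s): ", paste(unique(dup), collapse = ", ")))
  }
  lex <- structure(
    list(
      axis = axis,
      concepts = as_tibble(concepts),
      surface_index = list(),
      max_key_tokens = 0L,
      blacklist = character()
    ),
    class = "lexicon"
  )
  build_surface_index(lex)
}

#' @export
print.lexicon <- function(x, ...) {
  cat(sprintf(
    "<lexicon> axis=%s: %d concepts (%d obsolete), %d surface forms, %d blacklisted\n",
    x$axis, nrow(x$concepts), sum(x$concepts$obsolete),
    length(x$surface_index), length(x$blacklist)
  ))
  invisible(x)
}

#' Load an OBO ontology into a lexicon
#'
#' Minimal OBO 1.2 flat-file reader for `[Term]` stanzas: `id`, `name`,
#' `synonym` (all scopes indexed equally), `is_a` and `is_obsolete` are
#' honored; other tags are ignored. Obsolete terms are loaded (so ids in gold
#' files still resolve) but excluded from the surface index.
#'
#' @param path path to an OBO file.
#' @param axis annotation axis the ontology serves, `"BP"` or `"D"`.
#' @return a [new_lexicon()] object.
#' @export
load_obo <- function(path, axis = "BP") {
  assert_axis(axis)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  term_starts <- which(trimws(lines) == "[Term]")
  if (length(term_starts) == 0L) {
    return(new_lexicon(empty_concepts(), axis))
  }
  stanza_ends <- c(term_starts[-1] - 1L, length(lines))
  # a stanza actually ends at the next stanza header of any type
  other_headers <- which(grepl("^\\[", trimws(lines)))
  rows <- purrr::map2(term_starts, stanza_ends, function(s, e) {
    nxt <- other_headers[other_headers > s]
    if (length(nxt)) e <- min(e, nxt[1] - 1L)
    parse_obo_stanza(lines[(s + 1L):e], stanza_line = s)
  })
  concepts <- bind_rows(rows)
  dup <- concepts$id[duplicated(concepts$id)]
  if (length(dup)) {
    abort(paste0("duplicate concept id(s) in ", path, ": ",
                 paste(unique(dup), collapse = ", ")))
  }
  new_lexicon(concepts, axis)
}

parse_obo_stanza <- function(body, stanza_line) {
  kv <- stringi::stri_match_first_regex(body, "^([A-Za-z_]+):\\s*(.*)$")
  keys <- kv[, 2]
  vals <- kv[, 3]
  get1 <- function(k) vals[which(keys == k)[1]]
  id <- get1("id")
  name <- get1("name")
  if (is.na(id) || !nzchar(id) || is.na(name) || !nzchar(name)) {
    abort(sprintf(
      "malformed OBO stanza starting at line %d: missing %s",
      stanza_line, if (is.na(id) || !nzchar(id)) "id" else "name"
    ))
  }
  syn_raw <- vals[keys == "synonym" & !is.na(keys)]
  syns <- stringi::stri_match_first_regex(syn_raw, "^\"(.*?)\"")[, 2]
  syns <- syns[!is.na(syns) & nzchar(syns)]
  isa_raw <- vals[keys == "is_a" & !is.na(keys)]
  parents <- trimws(stringi::stri_replace_first_regex(isa_raw, "\\s*!.*$", ""))
  parents <- parents[nzchar(parents)]
  obsolete <- identical(tolower(trimws(get1("is_obsolete"))), "true")
  tibble(
    id = id, preferred_label = name,
    synonyms = list(unique(syns)),
    parent_ids = list(unique(parents)),
    obsolete = obsolete
  )
}

empty_concepts <- function() {
  tibble(
    id = character(), preferred_label = character(),
    synonyms = list(), parent_ids = list(), obsolete = logical()
  )
}

#' Load a TSV terminology into a lexicon
#'
#' Reads a disease-style terminology: a UTF-8 TSV with a header row and
#' columns `id`, `preferred_label`, `synonyms` (pipe-separated, possibly
#' empty) and optionally `parent_ids` (pipe-separated).
#'
#' @inheritParams load_obo
#' @return a [new_lexicon()] object.
#' @export
load_tsv_terminology <- function(path, axis = "D") {
  assert_axis(axis)
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  need <- c("id", "preferred_label")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    abort(paste0(path, ": missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  blank <- which(is.na(tab$id) | !nzchar(trimws(tab$id)))
  if (length(blank)) {
    abort(sprintf("%s: blank id on data line %s", path,
                  paste(blank, collapse = ", ")))
  }
  split_pipe <- function(x) {
    if (is.null(x)) return(rep(list(character()), nrow(tab)))
    lapply(x, function(v) {
      if (is.na(v) || !nzchar(trimws(v))) character()
      else trimws(stringi::stri_split_fixed(v, "|")[[1]])
    })
  }
  concepts <- tibble(
    id = trimws(tab$id),
    preferred_label = tab$preferred_label,
    synonyms = split_pipe(tab[["synonyms"]]),
    parent_ids = split_pipe(tab[["parent_ids"]]),
    obsolete = FALSE
  )
  new_lexicon(concepts, axis)
}

#' Read a gene/protein lexicon
#'
#' TSV with columns `accession` (e.g. `NX_P43403`), `symbol`, and `synonyms`
#' (pipe-separated, possibly empty). Each row becomes one gene entry usable as
#' the subject of a triage query.
#'
#' @param path path to the TSV file.
#' @return a tibble with columns `accession`, `symbol`, `synonyms`
#'   (list-column).
#' @export
read_gene_lexicon <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  need <- c("accession", "symbol")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    abort(paste0(path, ": missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  tibble(
    accession = tab$accession,
    symbol = tab$symbol,
    synonyms = lapply(tab[["synonyms"]], function(v) {
      if (is.null(v) || is.na(v) || !nzchar(trimws(v))) character()
      else trimws(stringi::stri_split_fixed(v, "|")[[1]])
    })
  )
}

#' Select one gene entry from a gene lexicon
#'
#' @param genes a tibble from [read_gene_lexicon()].
#' @param symbol gene symbol to look up (exact, case-insensitive).
#' @return a list with `accession`, `symbol`, `synonyms`.
#' @export
gene_entry <- function(genes, symbol) {
  hit <- which(toupper(genes$symbol) == toupper(symbol))
  if (length(hit) == 0L) {
    near <- genes$symbol[order(utils::adist(toupper(genes$symbol),
                                            toupper(symbol)))]
    abort(paste0(
      "unknown gene symbol \"", symbol, "\"; nearest known symbols: ",
      paste(utils::head(near, 3L), collapse = ", ")
    ))
  }
  list(
    accession = genes$accession[hit[1]],
    symbol = genes$symbol[hit[1]],
    synonyms = genes$synonyms[[hit[1]]]
  )
}

#' (Re)build the normalized surface-form index of a lexicon
#'
#' Every non-obsolete concept's preferred label and every synonym is indexed
#' under its normalized token-sequence key (NFKC, case-folded, punctuation as
#' separators), so hyphen/en-dash variants collapse to one key. Ambiguous
#' surface forms keep all their concept ids. Rebuilding is idempotent.
#'
#' @param lexicon a [new_lexicon()] object.
#' @return the lexicon with `surface_index` and `max_key_tokens` populated.
#' @export
build_surface_index <- function(lexicon) {
  stopifnot(inherits(lexicon, "lexicon"))
  cc <- lexicon$concepts
  idx <- new.env(parent = emptyenv())
  active <- which(!cc$obsolete)
  for (i in active) {
    forms <- unique(c(cc$preferred_label[i], cc$synonyms[[i]]))
    keys <- surface_key(forms)
    keys <- unique(keys[nzchar(keys)])
    for (k in keys) {
      idx[[k]] <- unique(c(idx[[k]], cc$id[i]))
    }
  }
  keys <- sort(ls(idx))
  lexicon$surface_index <- setNames(lapply(keys, function(k) sort(idx[[k]])), keys)
  lexicon$max_key_tokens <-
    if (length(keys)) max(stringi::stri_count_fixed(keys, " ") + 1L) else 0L
  lexicon
}

#' Load a concept blacklist into a lexicon
#'
#' Reads a plain-text file of concept ids, one per line (`#` comments and
#' blank lines allowed), and flags them on the lexicon. Blacklisted concepts
#' stay in the lexicon and are still extracted by the matcher; filtering
#' happens at candidate-proposal time so evaluation can count them.
#'
#' @param path path to the blacklist file.
#' @param lexicon a [new_lexicon()] object.
#' @return the lexicon with `blacklist` populated; ids absent from the lexicon
#'   are reported with a warning and kept in attribute `"unknown_ids"` on the
#'   returned lexicon.
#' @export
load_blacklist <- function(path, lexicon) {
  stopifnot(inherits(lexicon, "lexicon"))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(stringi::stri_replace_first_regex(lines, "#.*$", ""))
  ids <- unique(lines[nzchar(lines)])
  known <- ids[ids %in% lexicon$concepts$id]
  unknown <- setdiff(ids, known)
  if (length(unknown)) {
    warn(paste0("blacklist ids not in lexicon (ignored): ",
                paste(unknown, collapse = ", ")))
  }
  lexicon$blacklist <- union(lexicon$blacklist, known)
  attr(lexicon, "unknown_ids") <- unknown
  lexicon
}

#' is_a ancestor closure of a concept
#'
#' @param lexicon a lexicon.
#' @param id concept id.
#' @param include_self include `id` itself (default `TRUE`).
#' @return character vector of ancestor ids.
#' @export
concept_ancestors <- function(lexicon, id, include_self = TRUE) {
  parents <- setNames(lexicon$concepts$parent_ids, lexicon$concepts$id)
  seen <- character()
  frontier <- id
  while (length(frontier)) {
    nxt <- unique(unlist(parents[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, seen)
    seen <- c(seen, frontier)
    frontier <- nxt[nxt %in% names(parents)]
  }
  anc <- unique(seen)
  if (!include_self) anc <- setdiff(anc, id)
  anc
}

# root ids = concepts with no parents
lexicon_roots <- function(lexicon) {
  lexicon$concepts$id[lengths(lexicon$concepts$parent_ids) == 0L]
}

#' Do two concepts share an ontology branch?
#'
#' Two concepts are in the same branch when they share at least one non-root
#' is_a ancestor (each concept counts as its own ancestor, so a parent and its
#' descendant always share a branch).
#'
#' @param lexicon a lexicon.
#' @param id_a,id_b concept ids.
#' @return logical.
#' @export
same_branch <- function(lexicon, id_a, id_b) {
  roots <- lexicon_roots(lexicon)
  a <- setdiff(concept_ancestors(lexicon, id_a), roots)
  b <- setdiff(concept_ancestors(lexicon, id_b), roots)
  length(intersect(a, b)) > 0L
}

#' Serialize a lexicon to a canonical plain-text form
#'
#' Used by determinism tests: two loads of the same file yield byte-identical
#' serializations.
#'
#' @param lexicon a lexicon.
#' @return a single string.
#' @export
serialize_lexicon <- function(lexicon) {
  cc <- dplyr::arrange(lexicon$concepts, .data$id)
  conc <- vapply(seq_len(nrow(cc)), FUN.VALUE = character(1), function(i) {
    paste0(cc$id[i], "\t", cc$preferred_label[i], "\t",
           paste(sort(cc$synonyms[[i]]), collapse = "|"), "\t",
           paste(sort(cc$parent_ids[[i]]), collapse = "|"), "\t",
           cc$obsolete[i])
  })
  idx <- vapply(names(lexicon$surface_index), FUN.VALUE = character(1),
                function(k) paste0(k, " -> ",
                                   paste(lexicon$surface_index[[k]],
                                         collapse = ",")))
  paste(c(lexicon$axis, conc, idx, sort(lexicon$blacklist)), collapse = "\n")
}

#' @exportS3Method generics::glance
glance.lexicon <- function(x, ...) {
  tibble(
    axis = x$axis,
    n_concepts = nrow(x$concepts),
    n_obsolete = sum(x$concepts$obsolete),
    n_surface_forms = length(x$surface_index),
    n_ambiguous_forms = sum(lengths(x$surface_index) > 1L),
    n_blacklisted = length(x$blacklist)
  )
}
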