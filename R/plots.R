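#' Plot triage score components by rank
#'
#' Shows, for each ranked document, the three normalized score components
#' stacked against the final score — the quickest way to see whether a
#' ranking is BM25-driven or concept-driven.
#'
#' @param object a `triage_ranking` from [triage()].
#' @param ... ignored.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.triage_ranking <- function(object, ...) {
  df <- as_tibble(object) |>
    select("rank", "bm25_norm", "range_score", "tfidf_norm") |>
    tidyr::pivot_longer(-"rank", names_to = "component", values_to = "score")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$score,
                                   fill = .data$component)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = "rank", y = "normalized component score",
                  title = "Triage score composition by rank") +
    ggplot2::theme_minimal()
}

#' Plot the inter-annotator common-concept histogram
#'
#' @param iaa the result of [iaa_concepts()].
#' @return a ggplot object.
#' @export
plot_iaa_histogram <- function(iaa) {
  ggplot2::ggplot(iaa$histogram,
                  ggplot2::aes(x = factor(.data$common_classes),
                               y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "concepts found by both curators",
                  y = "abstracts",
                  title = sprintf(
                    "Common concepts per abstract (mean agreement %.0f%%)",
                    iaa$mean_agreement_pct)) +
    ggplot2::theme_minimal()
}

#' Plot a per-term rejection table
#'
#' Horizontal stacked bars of rejected / modified / accepted proportions for
#' the most-rejected proposed concepts.
#'
#' @param rejection a tibble from [term_rejection_table()].
#' @param top_n number of concepts to show (default 15).
#' @return a ggplot object.
#' @export
plot_rejection_table <- function(rejection, top_n = 15L) {
  lab_col <- if ("label" %in% names(rejection)) "label" else "concept_id"
  df <- utils::head(rejection, top_n)
  df$term <- factor(df[[lab_col]], levels = rev(df[[lab_col]]))
  long <- tidyr::pivot_longer(
    df[, c("term", "rejected", "modified", "accepted")],
    -"term", names_to = "action", values_to = "count"
  )
  long$action <- factor(long$action,
                        levels = c("accepted", "modified", "rejected"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$count, y = .data$term,
                                     fill = .data$action)) +
    ggplot2::geom_col(position = "fill") +
    ggplot2::labs(x = "proportion of reviews", y = NULL,
                  title = "Review outcomes for frequently proposed concepts") +
    ggplot2::theme_minimal()
}

#' Tidy a triage ranking
#'
#' @param x a `triage_ranking`.
#' @param ... ignored.
#' @return a plain tibble of the ranking.
#' @exportS3Method generics::tidy
tidy.triage_ranking <- function(x, ...) {
  as_tibble(x)
}
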