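#' Round half up
#'
#' Integer rounding used for every reported percentage: halves round away from
#' zero toward positive infinity (so 22.5 -> 23), unlike [round()]'s banker's
#' rounding. Keeping one convention package-wide makes the printed evaluation
#' tables reproducible.
#'
#' @param x numeric vector.
#' @return integer vector.
#' @examples
#' round_half_up(c(16.5, 22.4, 66.94))
#' @export
round_half_up <- function(x) {
  as.integer(floor(x + 0.5))
}

#' Integer percentage with half-up rounding
#'
#' @param num,den numerator and denominator.
#' @return integer percent, `round_half_up(100 * num / den)`.
#' @export
pct_half_up <- function(num, den) {
  round_half_up(100 * num / den)
}

# NFKC compatibility normalization + case folding; the single text-normal
# contract shared by tokenizer and surface index.
norm_fold <- function(x) {
  stringi::stri_trans_tolower(stringi::stri_trans_nfkc(x))
}

# Normalized token-sequence key for a surface form ("T-cell activation" and
# "T cell activation" share the key "t cell activation").
surface_key <- function(x) {
  vapply(
    x,
    FUN.VALUE = character(1),
    USE.NAMES = FALSE,
    FUN = function(s) paste(normalize_tokens(s)$surface, collapse = " ")
  )
}

assert_axis <- function(axis) {
  if (!is.character(axis) || length(axis) != 1L || !axis %in% c("BP", "D")) {
    abort("`axis` must be \"BP\" (biological process) or \"D\" (disease).")
  }
  axis
}

# stable sort helper: order by key descending with original order as final tie
order_desc_stable <- function(key) {
  order(-key, seq_along(key))
}
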