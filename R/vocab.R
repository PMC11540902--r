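#' Load the controlled vocabulary for quota notes
#'
#' Quota scope notes are free text written against a small controlled
#' vocabulary of trade terms (the commodity: live, skins, meat, ...), source
#' codes (wild, captive, ranched, F1, ...) and purpose codes (commercial,
#' hunting, ...). The bundled vocabulary maps every recognized token to its
#' canonical code and dimension; Malaysian region tags (Sabah, Sarawak,
#' Peninsular Malaysia) are a fourth dimension used when summing regional
#' quotas to the national level.
#'
#' A separate comparability table flags which terms are convertible to
#' whole-animal counts: a quota mixing countable and non-countable terms
#' (e.g. skins with meat) cannot be verified against specimen-count trade
#' volumes and is marked non-comparable.
#'
#' @param vocab_file,comparability_file Paths to CSV files; defaults are the
#'   vocabulary bundled with the package. Supplying your own files lets you
#'   extend the grammar without touching code.
#' @return A list with elements `tokens` (tibble: token, dimension,
#'   canonical) and `countable` (named logical vector by canonical term).
#' @export
#' @examples
#' v <- quota_vocabulary()
#' head(v$tokens)
quota_vocabulary <- function(vocab_file = NULL, comparability_file = NULL) {
  vocab_file <- vocab_file %||%
    system.file("extdata", "quota_vocabulary.csv", package = "quotawatch")
  comparability_file <- comparability_file %||%
    system.file("extdata", "term_comparability.csv", package = "quotawatch")
  tokens <- readr::read_csv(vocab_file, show_col_types = FALSE,
                            progress = FALSE)
  stopifnot(all(c("token", "dimension", "canonical") %in% names(tokens)))
  tokens$token <- normalize_text(tokens$token)
  comp <- readr::read_csv(comparability_file, show_col_types = FALSE,
                          progress = FALSE)
  countable <- stats::setNames(as.logical(comp$countable), comp$term)
  list(tokens = tokens, countable = countable)
}
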