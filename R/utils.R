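#' Round half away from zero
#'
#' Commercial ("half-up") rounding. Base [round()] rounds half to even, which
#' disagrees with how compliance percentages are conventionally reported
#' (e.g. 95.55 -> 95.6, not 95.5).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(0.5)        # 1
#' round_half_up(95.55, 1)   # 95.6
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Normalize free text for token matching
#'
#' Unicode NFC normalization, case folding and whitespace squashing, so that
#' vocabulary lookups are insensitive to case, stray spaces and composed vs
#' decomposed accents.
#'
#' @param x Character vector.
#' @return Normalized character vector.
#' @keywords internal
normalize_text <- function(x) {
  x <- stringi_nfc(x)
  x <- tolower(trimws(x))
  gsub("[[:space:]]+", " ", x)
}

# NFC via base enc2utf8 + stringr (stringi is a tidyverse dependency)
stringi_nfc <- function(x) {
  x <- enc2utf8(as.character(x))
  if (requireNamespace("stringi", quietly = TRUE)) {
    stringi::stri_trans_nfc(x)
  } else {
    x
  }
}

#' Derive a reproducible child seed from a master seed
#'
#' Splits one user-facing seed into independent per-stream seeds so that each
#' generator stage can be re-run in isolation yet the whole scenario remains
#' byte-identical under the same master seed. Kept below 2^31 - 1.
#'
#' @param seed Master integer seed.
#' @param stream Character stream label (e.g. "quotas", "ledger").
#' @return A single integer seed.
#' @keywords internal
child_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587L + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
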