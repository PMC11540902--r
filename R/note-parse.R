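#' Parse a free-text quota note into a structured scope
#'
#' Published quota tables describe what each quota covers in a short free-text
#' note ("live", "all, wild-taken", "skins and meat", ...). The parser is a
#' token grammar over the controlled vocabulary rather than a lookup of
#' memorized strings: the note is split on commas, semicolons, "and" and
#' ampersands, each token is normalized (Unicode NFC, case and whitespace
#' folded) and classified as a term, source, purpose or region code.
#'
#' Defaults implement the convention that an unspecified source means
#' wild-sourced trade:
#' \itemize{
#'   \item missing/blank note: terms = ALL, sources = \{wild\},
#'     purposes = ALL;
#'   \item tokens present but no source token and no "all": sources default
#'     to \{wild\};
#'   \item a bare "all": every dimension ALL;
#'   \item "all" paired with detail: only the detailed dimensions are
#'     constrained, the rest are ALL (so "all, live" covers live trade from
#'     all sources for all purposes).
#' }
#' Unrecognized tokens raise a record-level warning and are preserved in the
#' scope's `unparsed` bucket, never silently dropped. A scope whose term set
#' mixes units not convertible to individual animals (e.g. skins with meat)
#' is flagged `comparable = FALSE`.
#'
#' @param note A single note string, or `NA`.
#' @param vocab Controlled vocabulary from [quota_vocabulary()].
#' @param warn Emit warnings for unrecognized tokens? Default `TRUE`.
#' @return A [quota_scope()].
#' @export
#' @examples
#' v <- quota_vocabulary()
#' parse_quota_note("live", v)
#' parse_quota_note("all, live", v)
#' parse_quota_note(NA, v)
parse_quota_note <- function(note, vocab = quota_vocabulary(), warn = TRUE) {
  if (is.null(note) || length(note) == 0 || is.na(note) ||
      !nzchar(trimws(note))) {
    return(quota_scope(terms = "ALL", sources = "wild", purposes = "ALL",
                       comparable = TRUE))
  }
  toks <- tokenize_note(note)
  has_all <- "all" %in% toks
  toks <- setdiff(toks, "all")

  lut <- vocab$tokens
  idx <- match(toks, lut$token)
  known <- !is.na(idx)
  unparsed <- toks[!known]
  if (warn && length(unparsed)) {
    warning("unrecognized quota-note token(s): ",
            paste(unparsed, collapse = ", "), call. = FALSE)
  }
  dimension <- lut$dimension[idx[known]]
  canonical <- lut$canonical[idx[known]]

  terms <- unique(canonical[dimension == "term"])
  sources <- unique(canonical[dimension == "source"])
  purposes <- unique(canonical[dimension == "purpose"])
  region <- unique(canonical[dimension == "region"])
  region <- if (length(region)) region[1] else NA_character_

  if (!length(terms)) terms <- "ALL"
  if (!length(purposes)) purposes <- "ALL"
  if (!length(sources)) sources <- if (has_all) "ALL" else "wild"

  quota_scope(terms = terms, sources = sources, purposes = purposes,
              comparable = terms_comparable(terms, vocab),
              region = region, unparsed = unparsed)
}

tokenize_note <- function(note) {
  x <- normalize_text(note)
  # "and" both separates tokens ("skins and meat") and occurs inside
  # multi-word vocabulary entries; split conservatively on list separators
  x <- gsub("\\band\\b|&", ",", x)
  toks <- strsplit(x, "[,;]")[[1]]
  toks <- trimws(gsub("[[:space:]]+", " ", toks))
  toks[nzchar(toks)]
}

#' Parse many notes into scope columns
#'
#' Vectorized wrapper around [parse_quota_note()] returning one row per note
#' with canonical dimension strings, ready to bind onto a quota table.
#'
#' @param notes Character vector (NA allowed).
#' @inheritParams parse_quota_note
#' @return A tibble with columns `terms`, `sources`, `purposes`, `scope`
#'   (full canonical string), `comparable`, `region`, `unparsed`.
#' @export
parse_quota_notes <- function(notes, vocab = quota_vocabulary(),
                              warn = TRUE) {
  scopes <- lapply(notes, parse_quota_note, vocab = vocab, warn = warn)
  tibble::tibble(
    terms = vapply(scopes, function(s) dim_string(s$terms), ""),
    sources = vapply(scopes, function(s) dim_string(s$sources), ""),
    purposes = vapply(scopes, function(s) dim_string(s$purposes), ""),
    scope = vapply(scopes, format_scope, ""),
    comparable = vapply(scopes, function(s) s$comparable, logical(1)),
    region = vapply(scopes, function(s) s$region, ""),
    unparsed = vapply(scopes, function(s)
      paste(s$unparsed, collapse = "+"), "")
  )
}
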