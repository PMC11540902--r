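#' Quota scope: which trade a quota covers
#'
#' A scope restricts a quota to combinations of trade term, source and
#' purpose. Each dimension is either the sentinel `"ALL"` (covers anything)
#' or a set of canonical codes. Scopes come from parsing the free-text
#' "notes" column of published quota tables ([parse_quota_note()]).
#'
#' @param terms,sources,purposes Character vectors of canonical codes, or
#'   `"ALL"`.
#' @param comparable Logical: are all terms convertible to whole-animal
#'   counts (so that the quota can be verified against specimen-count trade)?
#' @param region Region tag (Malaysian quotas), or `NA`.
#' @param unparsed Character vector of tokens the grammar did not recognize.
#' @return An object of class `quota_scope`.
#' @export
quota_scope <- function(terms = "ALL", sources = "ALL", purposes = "ALL",
                        comparable = TRUE, region = NA_character_,
                        unparsed = character()) {
  dims <- list(terms = terms, sources = sources, purposes = purposes)
  for (nm in names(dims)) {
    d <- dims[[nm]]
    if (length(d) == 0) stop("scope dimension '", nm, "' must be non-empty")
    if ("ALL" %in% d && length(d) > 1)
      stop("'ALL' is exclusive with enumerated members in '", nm, "'")
    dims[[nm]] <- sort(unique(d))
  }
  structure(c(dims, list(comparable = isTRUE(comparable), region = region,
                         unparsed = unparsed)),
            class = "quota_scope")
}

#' @export
print.quota_scope <- function(x, ...) {
  cat("<quota_scope> ", format_scope(x), "\n", sep = "")
  if (length(x$unparsed))
    cat("  unparsed tokens: ", paste(x$unparsed, collapse = ", "), "\n")
  invisible(x)
}

#' Canonical string form of a scope (or one scope dimension)
#'
#' The canonical form is stable under re-parsing: `parse_scope_string(
#' format_scope(s))` equals `s` up to the unparsed bucket.
#'
#' @param scope A `quota_scope`.
#' @return A single string like `"terms=live;sources=wild;purposes=ALL"`.
#' @export
format_scope <- function(scope) {
  paste0("terms=", dim_string(scope$terms),
         ";sources=", dim_string(scope$sources),
         ";purposes=", dim_string(scope$purposes))
}

dim_string <- function(d) paste(sort(unique(d)), collapse = "+")

dim_unstring <- function(s) sort(unique(strsplit(s, "+", fixed = TRUE)[[1]]))

#' @rdname format_scope
#' @param x Canonical scope string.
#' @param vocab Controlled vocabulary (for re-deriving comparability).
#' @export
parse_scope_string <- function(x, vocab = quota_vocabulary()) {
  parts <- strsplit(x, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  terms <- dim_unstring(vals[["terms"]])
  quota_scope(terms = terms,
              sources = dim_unstring(vals[["sources"]]),
              purposes = dim_unstring(vals[["purposes"]]),
              comparable = terms_comparable(terms, vocab))
}

terms_comparable <- function(terms, vocab) {
  if (identical(terms, "ALL")) return(TRUE)
  known <- terms %in% names(vocab$countable)
  all(known) && all(vocab$countable[terms])
}

#' Does a scope cover a (term, source, purpose) combination?
#'
#' Vectorized over the record columns: each dimension covers a value iff the
#' dimension is `"ALL"` or the value is one of its members.
#'
#' @param terms_str,sources_str,purposes_str Canonical dimension strings of
#'   the scope (see [format_scope()]); scalars.
#' @param term,source,purpose Record values; vectors of common length.
#' @return Logical vector.
#' @export
scope_covers <- function(terms_str, sources_str, purposes_str,
                         term, source, purpose) {
  dim_covers(terms_str, term) &
    dim_covers(sources_str, source) &
    dim_covers(purposes_str, purpose)
}

dim_covers <- function(dim_str, value) {
  if (identical(dim_str, "ALL")) return(rep(TRUE, length(value)))
  value %in% dim_unstring(dim_str)
}

#' Do two scopes intersect?
#'
#' Two scopes overlap when some (term, source, purpose) combination is
#' covered by both, i.e. every dimension pair intersects ("ALL" intersects
#' anything). Used to find quotas published at conflicting specificities for
#' the same exporter, taxon and year, which cannot be matched to trade
#' unambiguously.
#'
#' @param a,b Canonical scope strings ([format_scope()]).
#' @return Logical scalar.
#' @export
scopes_overlap <- function(a, b) {
  pa <- scope_string_parts(a); pb <- scope_string_parts(b)
  all(vapply(names(pa), function(nm) dims_intersect(pa[[nm]], pb[[nm]]),
             logical(1)))
}

scope_string_parts <- function(x) {
  parts <- strsplit(x, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  stats::setNames(lapply(kv, function(p) dim_unstring(p[2])),
                  vapply(kv, `[`, "", 1))
}

dims_intersect <- function(a, b) {
  "ALL" %in% a || "ALL" %in% b || length(intersect(a, b)) > 0
}
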