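#' Read a quota table in the Species+ CSV dialect
#'
#' Expects one row per published quota with the exporting party, year, taxon
#' name and rank, the quota amount and the free-text scope note. Column names
#' are remapped through `header_map` so exports with different headers can be
#' read without editing the file.
#'
#' @param file Path to CSV.
#' @param header_map Named character vector mapping file headers to the
#'   canonical names `party`, `year`, `taxon`, `rank`, `amount`, `notes`,
#'   e.g. `c(Party = "party", Quota = "amount")`. Canonical headers pass
#'   through unchanged.
#' @return A tibble of raw quota rows (`party`, `year`, `taxon`, `rank`,
#'   `amount`, `notes`). Amounts are kept as-is, including the `-1` sentinel
#'   and `NA`.
#' @export
read_quota_csv <- function(file, header_map = NULL) {
  df <- readr::read_csv(file, show_col_types = FALSE, progress = FALSE)
  df <- apply_header_map(df, header_map)
  need <- c("party", "year", "taxon", "rank", "amount", "notes")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("quota CSV lacks column(s): ", paste(missing, collapse = ", "))
  out <- tibble::as_tibble(df[need])
  out$year <- as.integer(out$year)
  out$amount <- suppressWarnings(as.numeric(out$amount))
  out$notes <- as.character(out$notes)
  if (any(!nzchar(out$party) | is.na(out$party)))
    stop("quota rows with empty party code")
  out
}

apply_header_map <- function(df, header_map) {
  if (is.null(header_map)) return(df)
  hit <- names(df) %in% names(header_map)
  names(df)[hit] <- unname(header_map[names(df)[hit]])
  df
}

#' Remove exact duplicate quota rows
#'
#' Drops rows where every field is identical, keeping the first occurrence
#' (order-stable). Rows differing in any field — including only the amount —
#' are all kept.
#'
#' @param rows Raw quota tibble.
#' @return List with `rows` (deduplicated, original order) and `removed`
#'   (the dropped duplicates).
#' @export
deduplicate_quotas <- function(rows) {
  dup <- duplicated(rows)
  list(rows = rows[!dup, , drop = FALSE],
       removed = rows[dup, , drop = FALSE])
}

#' Remove back-dated quotas created by taxonomic splits
#'
#' When a species is split out of another at a Conference of the Parties,
#' public registries sometimes back-date the parent's historical quotas onto
#' the newly accepted child taxon — years before the child formally existed.
#' Assessing the child against those quotas would be wrong. Given an explicit
#' table of split events, this drops any child-taxon quota dated before the
#' adoption year that duplicates a parent-taxon quota in the same party and
#' year with the same amount and notes. A pre-adoption child quota with no
#' matching parent quota is kept (it is not a duplicate) but flagged.
#'
#' @param rows Raw quota tibble.
#' @param split_events Tibble/data.frame with columns `parent_taxon`,
#'   `child_taxon`, `adoption_year`.
#' @return List with `rows` (kept, original order), `removed`, and
#'   `flagged_orphans` (pre-adoption child quotas without a parent match).
#' @export
drop_backdated_split_quotas <- function(rows, split_events) {
  if (is.null(split_events) || nrow(split_events) == 0)
    return(list(rows = rows, removed = rows[0, ], flagged_orphans = rows[0, ]))
  drop <- rep(FALSE, nrow(rows))
  orphan <- rep(FALSE, nrow(rows))
  for (e in seq_len(nrow(split_events))) {
    child <- split_events$child_taxon[e]
    parent <- split_events$parent_taxon[e]
    adopt <- split_events$adoption_year[e]
    if (!any(rows$taxon %in% c(child, parent)))
      warning("split event names taxa absent from quota table: ",
              parent, " / ", child, call. = FALSE)
    cand <- which(rows$taxon == child & rows$year < adopt)
    for (i in cand) {
      match_parent <- rows$taxon == parent &
        rows$party == rows$party[i] &
        rows$year == rows$year[i] &
        same_value(rows$amount, rows$amount[i]) &
        same_value(rows$notes, rows$notes[i])
      if (any(match_parent)) drop[i] <- TRUE else orphan[i] <- TRUE
    }
  }
  list(rows = rows[!drop, , drop = FALSE],
       removed = rows[drop, , drop = FALSE],
       flagged_orphans = rows[orphan, , drop = FALSE])
}

same_value <- function(v, x) {
  if (is.na(x)) is.na(v) else !is.na(v) & v == x
}

#' Resolve subspecies recorded at species rank
#'
#' Registries occasionally record a trinomial taxon name while stating the
#' rank as species. Such rows are collapsed to the binomial (first two name
#' parts) and flagged `subspecies_resolved`. Rows whose rank is explicitly
#' `subspecies`, and binomial rows, pass through unchanged.
#'
#' @param rows Raw quota tibble.
#' @return The tibble with `taxon` corrected and a logical
#'   `subspecies_resolved` column.
#' @export
resolve_subspecies <- function(rows) {
  parts <- strsplit(trimws(rows$taxon), "[[:space:]]+")
  n_parts <- lengths(parts)
  fix <- rows$rank == "species" & n_parts >= 3
  rows$subspecies_resolved <- fix
  rows$taxon[fix] <- vapply(parts[fix],
                            function(p) paste(p[1:2], collapse = " "), "")
  rows
}

#' Remove structurally unusable quota rows
#'
#' Partitions the input into usable rows and removed rows with reasons:
#' \describe{
#'   \item{sentinel_amount}{amount is the `-1` sentinel or missing
#'     (unverifiable permit bookkeeping);}
#'   \item{multi_year_span}{the note dates the quota across two calendar
#'     years (e.g. "March 2012 to March 2013"), so it cannot be matched to
#'     annual trade totals;}
#'   \item{reexport_only}{the note restricts the quota to re-exports, which
#'     are excluded from direct-export compliance.}
#' }
#'
#' @param rows Raw quota tibble.
#' @return List with `kept` and `removed` (with a `reason` column);
#'   together they partition the input.
#' @export
filter_invalid_quotas <- function(rows) {
  notes <- ifelse(is.na(rows$notes), "", normalize_text(rows$notes))
  reason <- rep(NA_character_, nrow(rows))
  reason[grepl("re-?export", notes)] <- "reexport_only"
  reason[multi_year_note(notes)] <- "multi_year_span"
  reason[is.na(rows$amount) | rows$amount == -1] <- "sentinel_amount"
  keep <- is.na(reason)
  removed <- rows[!keep, , drop = FALSE]
  removed$reason <- reason[!keep]
  list(kept = rows[keep, , drop = FALSE], removed = removed)
}

multi_year_note <- function(notes) {
  months <- paste0("(january|february|march|april|may|june|july|august|",
                   "september|october|november|december)")
  span <- paste0(months, "[[:space:]]+([0-9]{4}).*(to|until|-|–)",
                 ".*", months, "[[:space:]]+([0-9]{4})")
  m <- regmatches(notes, regexec(span, notes))
  vapply(m, function(g) length(g) > 0 && g[3] != g[6], logical(1))
}

#' Clean a raw quota table into quota records
#'
#' Runs the full cleaning chain in order: exact deduplication, removal of
#' back-dated split quotas, subspecies resolution, validity filtering, then
#' note parsing into structured scopes. Each stage's removals are audited;
#' the chain is idempotent and the per-stage removal counts sum to
#' `nrow(input) - nrow(output)`.
#'
#' @param rows Raw quota tibble ([read_quota_csv()]).
#' @param split_events Split-event table for
#'   [drop_backdated_split_quotas()], or `NULL`.
#' @param vocab Controlled vocabulary ([quota_vocabulary()]).
#' @param warn Warn on unrecognized note tokens?
#' @return A list with:
#'   \describe{
#'     \item{quotas}{tibble of quota records: `id`, `party`, `year`,
#'       `taxon`, `rank`, `amount`, `is_zero`, scope columns (`terms`,
#'       `sources`, `purposes`, `scope`, `comparable`, `region`,
#'       `unparsed`), `provenance` and the original `notes`;}
#'     \item{audit}{tibble of per-stage removal counts;}
#'     \item{removed}{list of removed-row tibbles per stage.}
#'   }
#' @export
clean_quotas <- function(rows, split_events = NULL,
                         vocab = quota_vocabulary(), warn = TRUE) {
  n_in <- nrow(rows)
  d <- deduplicate_quotas(rows)
  s <- drop_backdated_split_quotas(d$rows, split_events)
  r <- resolve_subspecies(s$rows)
  f <- filter_invalid_quotas(r)
  kept <- f$kept

  scope_cols <- parse_quota_notes(kept$notes, vocab = vocab, warn = warn)
  quotas <- dplyr::bind_cols(kept[c("party", "year", "taxon", "rank",
                                    "amount")], scope_cols)
  quotas$amount <- as.integer(quotas$amount)
  quotas$is_zero <- quotas$amount == 0L
  quotas$notes <- kept$notes
  quotas$provenance <- ifelse(kept$subspecies_resolved,
                              "subspecies_resolved", "")
  quotas$id <- sprintf("q%05d", seq_len(nrow(quotas)))
  quotas <- dplyr::relocate(quotas, "id")

  dup_scope <- duplicated(quotas[c("party", "year", "taxon", "scope",
                                   "region")])
  if (warn && any(dup_scope))
    warning(sum(dup_scope), " cleaned quota record(s) share (party, year, ",
            "taxon, scope) with another record", call. = FALSE)

  audit <- tibble::tibble(
    stage = c("input", "deduplicate", "split_backdated", "invalid", "output"),
    removed = c(0L, nrow(d$removed), nrow(s$removed), nrow(f$removed), 0L),
    remaining = c(n_in, nrow(d$rows), nrow(s$rows), nrow(f$kept),
                  nrow(quotas)))
  list(quotas = quotas, audit = audit,
       removed = list(duplicates = d$removed, split_backdated = s$removed,
                      invalid = f$removed,
                      split_orphans = s$flagged_orphans))
}

#' Write a cleaning audit log as JSON lines
#'
#' @param clean Result of [clean_quotas()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_quota_audit <- function(clean, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(clean$audit))) {
    writeLines(jsonlite::toJSON(as.list(clean$audit[i, ]),
                                auto_unbox = TRUE), con)
  }
  invisible(path)
}
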