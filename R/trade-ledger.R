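#' Read a trade ledger in the CITES Trade Database CSV dialect
#'
#' Reads a comparative tabulation: one row per (year, taxon, term, unit,
#' importer, exporter, origin, purpose, source) with two quantity columns,
#' one for the exporter-reported volume and one for the importer-reported
#' volume. The table is pivoted to one record per reporter so downstream
#' aggregation can treat the two reporting perspectives symmetrically.
#'
#' Fractional quantities are rounded half-up to integers with a warning:
#' specimen counts are whole animals.
#'
#' @param file Path to CSV.
#' @param header_map Named character vector remapping file headers to the
#'   canonical names `year`, `taxon`, `term`, `unit`, `importer`,
#'   `exporter`, `origin`, `purpose`, `source`, `exporter_qty`,
#'   `importer_qty` (e.g. `c("Exporter reported quantity" =
#'   "exporter_qty")`).
#' @return Tibble of trade records: `year`, `taxon`, `exporter`, `importer`,
#'   `term`, `source`, `purpose`, `unit`, `origin`, `reporter`
#'   (`"exporter_reported"` / `"importer_reported"`), `quantity`.
#' @export
read_trade_csv <- function(file, header_map = NULL) {
  df <- readr::read_csv(file, show_col_types = FALSE, progress = FALSE)
  df <- apply_header_map(df, header_map)
  need <- c("year", "taxon", "term", "unit", "importer", "exporter",
            "origin", "purpose", "source", "exporter_qty", "importer_qty")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("trade CSV lacks column(s): ", paste(missing, collapse = ", "))
  df <- tibble::as_tibble(df[need])
  long <- tidyr::pivot_longer(df, c("exporter_qty", "importer_qty"),
                              names_to = "reporter", values_to = "quantity")
  long$reporter <- ifelse(long$reporter == "exporter_qty",
                          "exporter_reported", "importer_reported")
  long <- long[!is.na(long$quantity) & long$quantity > 0, , drop = FALSE]
  if (any(long$quantity < 0)) stop("negative trade quantities")
  frac <- long$quantity != floor(long$quantity)
  if (any(frac)) {
    warning(sum(frac), " fractional specimen count(s) rounded to integer",
            call. = FALSE)
    long$quantity <- round_half_up(long$quantity)
  }
  long$quantity <- as.integer(long$quantity)
  long$year <- as.integer(long$year)
  long$unit <- ifelse(is.na(long$unit), "", as.character(long$unit))
  long
}

#' Restrict a ledger to direct exports of live specimen counts
#'
#' Keeps records where the term is `live`, the unit denotes a number of
#' specimens (blank or "specimens" after normalization — any weight or other
#' unit is rejected), and the shipment is a direct export (origin missing or
#' equal to the exporter; anything else is a re-export). Idempotent.
#'
#' @param records Trade-record tibble ([read_trade_csv()]).
#' @return Filtered tibble.
#' @export
filter_live_direct <- function(records) {
  unit <- normalize_text(records$unit)
  ok_unit <- is.na(unit) | unit %in% c("", "specimens")
  direct <- is.na(records$origin) | records$origin == records$exporter
  records[records$term == "live" & ok_unit & direct, , drop = FALSE]
}

#' Aggregate traded volumes for one quota key under a scope
#'
#' Sums quantities of records matching a (taxon, exporter, year) key whose
#' (term, source, purpose) fall inside the quota's scope ("ALL" matches
#' anything), separately for exporter-reported and importer-reported
#' records.
#'
#' @param records Trade-record tibble.
#' @param terms_str,sources_str,purposes_str Canonical scope dimension
#'   strings of the quota.
#' @param taxon,exporter,year The quota key.
#' @return One-row tibble: `taxon`, `exporter`, `year`, `exporter_volume`,
#'   `importer_volume`.
#' @export
aggregate_volumes <- function(records, terms_str, sources_str, purposes_str,
                              taxon, exporter, year) {
  sel <- records$taxon == taxon & records$exporter == exporter &
    records$year == year &
    scope_covers(terms_str, sources_str, purposes_str,
                 records$term, records$source, records$purpose)
  sub <- records[sel, , drop = FALSE]
  tibble::tibble(
    taxon = taxon, exporter = exporter, year = year,
    exporter_volume = sum(sub$quantity[sub$reporter == "exporter_reported"]),
    importer_volume = sum(sub$quantity[sub$reporter == "importer_reported"]))
}

#' Match every quota to its traded volume
#'
#' Applies [aggregate_volumes()] to each quota record using the quota's own
#' scope and key.
#'
#' @param quotas Cleaned quota tibble ([clean_quotas()]).
#' @param records Trade-record tibble.
#' @return `quotas` with `exporter_volume` and `importer_volume` appended.
#' @export
build_volume_cells <- function(quotas, records) {
  cells <- purrr::pmap_dfr(
    quotas[c("terms", "sources", "purposes", "taxon", "party", "year")],
    function(terms, sources, purposes, taxon, party, year)
      aggregate_volumes(records, terms, sources, purposes,
                        taxon, party, year))
  quotas$exporter_volume <- cells$exporter_volume
  quotas$importer_volume <- cells$importer_volume
  quotas
}

#' Sum Malaysian regional quotas to the national level
#'
#' Malaysia publishes some quotas separately for Sabah, Sarawak and
#' Peninsular Malaysia, but trade ledgers record only the national exporter.
#' Regional quotas sharing (party, taxon, year, scope) are summed into one
#' national quota flagged `region_summed`; the sum is taken over whichever
#' regions are present. Quotas without a region tag pass through unchanged.
#'
#' @param quotas Cleaned quota tibble with a `region` column.
#' @return Tibble with regional rows replaced by national sums.
#' @export
sum_malaysian_regions <- function(quotas) {
  regional <- !is.na(quotas$region) & nzchar(quotas$region)
  if (!any(regional)) return(quotas)
  keep <- quotas[!regional, , drop = FALSE]
  reg <- quotas[regional, , drop = FALSE]
  summed <- reg |>
    dplyr::group_by(.data$party, .data$taxon, .data$year, .data$terms,
                    .data$sources, .data$purposes, .data$scope) |>
    dplyr::summarise(
      id = .data$id[1], rank = .data$rank[1],
      amount = as.integer(sum(.data$amount)),
      comparable = all(.data$comparable),
      region = NA_character_, unparsed = "",
      notes = paste(unique(stats::na.omit(.data$notes)), collapse = " | "),
      provenance = "region_summed",
      .groups = "drop")
  summed$is_zero <- summed$amount == 0L
  dplyr::bind_rows(keep, summed[names(keep)[names(keep) %in% names(summed)]])
}

#' Remove quotas with overlapping scopes for the same exporter, taxon and year
#'
#' Where a party publishes two quotas for the same taxon and year whose
#' scopes intersect (e.g. one for live wild specimens and another for live
#' specimens from all sources), traded volumes cannot be attributed to
#' either quota unambiguously; every member of the overlapping set is
#' dropped with an audit reason.
#'
#' @param quotas Cleaned quota tibble.
#' @return List with `kept` and `removed` (with `reason = "overlapping_scope"`).
#' @export
remove_overlapping_quotas <- function(quotas) {
  drop <- rep(FALSE, nrow(quotas))
  groups <- split(seq_len(nrow(quotas)),
                  paste(quotas$party, quotas$taxon, quotas$year, sep = "\r"))
  for (idx in groups) {
    if (length(idx) < 2) next
    for (a in seq_along(idx)) {
      for (b in seq_along(idx)) {
        if (a >= b) next
        if (scopes_overlap(quotas$scope[idx[a]], quotas$scope[idx[b]])) {
          drop[idx[a]] <- TRUE
          drop[idx[b]] <- TRUE
        }
      }
    }
  }
  removed <- quotas[drop, , drop = FALSE]
  if (nrow(removed)) removed$reason <- "overlapping_scope"
  list(kept = quotas[!drop, , drop = FALSE], removed = removed)
}

#' Exclude species whose live quota coexists with quotas under other terms
#'
#' A species with a low live quota but a separate skins or consumption quota
#' can legally ship many live animals under the non-live quota, making the
#' live quota unverifiable against live-trade volumes. For each party, taxa
#' holding both a live-covering quota and a quota under a disjoint non-live
#' term are excluded from the compliance set; `extra_exclusions` allows a
#' configured override list of (party, taxon) pairs.
#'
#' @param quotas Cleaned quota tibble.
#' @param extra_exclusions Optional tibble with columns `party`, `taxon`.
#' @return List with `kept` and `removed` (reason `"cross_term_quota"`).
#' @export
exclude_cross_term_species <- function(quotas, extra_exclusions = NULL) {
  has_live <- vapply(quotas$terms, function(t)
    identical(t, "ALL") || "live" %in% dim_unstring(t), logical(1))
  key <- paste(quotas$party, quotas$taxon, sep = "\r")
  live_keys <- unique(key[has_live & quotas$terms != "ALL"])
  other_keys <- unique(key[!has_live])
  bad <- intersect(live_keys, other_keys)
  drop <- key %in% bad
  if (!is.null(extra_exclusions) && nrow(extra_exclusions)) {
    drop <- drop | key %in% paste(extra_exclusions$party,
                                  extra_exclusions$taxon, sep = "\r")
  }
  removed <- quotas[drop, , drop = FALSE]
  if (nrow(removed)) removed$reason <- "cross_term_quota"
  list(kept = quotas[!drop, , drop = FALSE], removed = removed)
}
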