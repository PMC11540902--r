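#' Trade records not covered by any quota
#'
#' A record is quota-managed when some quota exists for its (taxon,
#' exporter, year) whose scope covers the record's (term, source, purpose).
#' Everything else is unmanaged trade. Genus- or family-level quotas are
#' excluded from coverage by default (`higher_rank_policy = "exclude"`):
#' whether a genus quota should shield its member species is a matching
#' policy, and the permissive alternative (`"aggregate"`, matching on the
#' quota taxon being a name prefix) is available as a switch.
#'
#' @param trade Trade-record tibble, pre-filtered to live, wild-sourced,
#'   direct, count-unit records (see [filter_live_direct()]).
#' @param quotas Cleaned quota tibble.
#' @param higher_rank_policy `"exclude"` (default) or `"aggregate"`.
#' @return List with `unmanaged` and `managed` trade-record tibbles
#'   (partitioning the input).
#' @export
unmanaged_trade <- function(trade, quotas,
                            higher_rank_policy = c("exclude", "aggregate")) {
  higher_rank_policy <- match.arg(higher_rank_policy)
  species_q <- quotas[quotas$rank %in% c("species", "subspecies"), ,
                      drop = FALSE]
  higher_q <- quotas[!quotas$rank %in% c("species", "subspecies"), ,
                     drop = FALSE]
  covered <- rep(FALSE, nrow(trade))
  qkey <- split(seq_len(nrow(species_q)),
                paste(species_q$taxon, species_q$party, species_q$year,
                      sep = "\r"))
  tkey <- paste(trade$taxon, trade$exporter, trade$year, sep = "\r")
  for (i in seq_len(nrow(trade))) {
    qi <- qkey[[tkey[i]]]
    if (is.null(qi)) next
    for (q in qi) {
      if (scope_covers(species_q$terms[q], species_q$sources[q],
                       species_q$purposes[q], trade$term[i],
                       trade$source[i], trade$purpose[i])) {
        covered[i] <- TRUE
        break
      }
    }
  }
  if (higher_rank_policy == "aggregate" && nrow(higher_q)) {
    for (q in seq_len(nrow(higher_q))) {
      hit <- startsWith(trade$taxon, paste0(sub(" .*", "", higher_q$taxon[q]),
                                            " ")) |
        trade$taxon == higher_q$taxon[q]
      hit <- hit & trade$exporter == higher_q$party[q] &
        trade$year == higher_q$year[q] &
        scope_covers(higher_q$terms[q], higher_q$sources[q],
                     higher_q$purposes[q], trade$term, trade$source,
                     trade$purpose)
      covered <- covered | hit
    }
  }
  list(unmanaged = trade[!covered, , drop = FALSE],
       managed = trade[covered, , drop = FALSE])
}

#' Resolve the IUCN category of a taxon at a given year
#'
#' "At the time of trade": the latest assessment whose `year_from` does not
#' postdate the trade year. Before any assessment — or for taxa absent from
#' the threat table — the category is `NE` (not evaluated).
#'
#' @param threats Threat tibble: `taxon`, `year_from`, `category`,
#'   `trade_threat_flag`.
#' @param taxon,year Vectors of equal length.
#' @return Character vector of categories.
#' @export
iucn_category_at <- function(threats, taxon, year) {
  threats <- threats[order(threats$taxon, threats$year_from), , drop = FALSE]
  vapply(seq_along(taxon), function(i) {
    tl <- threats[threats$taxon == taxon[i] &
                    threats$year_from <= year[i], , drop = FALSE]
    if (!nrow(tl)) "NE" else tl$category[nrow(tl)]
  }, "")
}

#' Yearly trends in unmanaged trade by conservation-concern category
#'
#' Crosses unmanaged trade with the threat table and tallies, per year and
#' category, the number of species-exporter combinations and the traded
#' volume. Categories are non-exclusive — a critically endangered species
#' flagged as likely threatened by trade contributes to both
#' `globally_threatened` and `trade_threatened`:
#' \describe{
#'   \item{dd_or_ne}{data deficient or not evaluated at the time of trade
#'     (taxa missing from the threat table are counted here, with a
#'     warning);}
#'   \item{globally_threatened}{VU, EN or CR at the time of trade;}
#'   \item{trade_threatened}{flagged as likely threatened by international
#'     trade.}
#' }
#' Era summaries (before/from `era_split`) report both counting conventions
#' for combinations: distinct combinations over the era and the sum of
#' yearly combination counts.
#'
#' @param unmanaged Unmanaged trade tibble ([unmanaged_trade()]).
#' @param threats Threat tibble (`taxon`, `year_from`, `category`,
#'   `trade_threat_flag`).
#' @param era_split First year of the recent era; default 2016.
#' @return List with `cells` (tibble: `year`, `category`, `n_combos`,
#'   `volume`) and `eras` (tibble per era and category: `n_combos_distinct`,
#'   `n_combo_years`, `n_species`, `n_exporters`, `volume`).
#' @export
gap_trends <- function(unmanaged, threats, era_split = 2016) {
  tr <- unmanaged
  if (!nrow(tr))
    return(list(cells = tibble::tibble(), eras = tibble::tibble()))
  missing <- setdiff(unique(tr$taxon), unique(threats$taxon))
  if (length(missing))
    warning(length(missing), " traded taxon/taxa absent from threat table; ",
            "counted as not evaluated", call. = FALSE)
  tr$category_at <- iucn_category_at(threats, tr$taxon, tr$year)
  flag <- threats[!duplicated(threats$taxon), c("taxon", "trade_threat_flag")]
  tr$trade_threat <- tr$taxon %in% flag$taxon[flag$trade_threat_flag]

  memberships <- list(
    dd_or_ne = tr$category_at %in% c("DD", "NE"),
    globally_threatened = tr$category_at %in% c("VU", "EN", "CR"),
    trade_threatened = tr$trade_threat)

  cells <- dplyr::bind_rows(lapply(names(memberships), function(cat) {
    sub <- tr[memberships[[cat]], , drop = FALSE]
    if (!nrow(sub)) return(tibble::tibble())
    sub |>
      dplyr::group_by(year = .data$year) |>
      dplyr::summarise(
        n_combos = dplyr::n_distinct(paste(.data$taxon, .data$exporter)),
        volume = sum(.data$quantity), .groups = "drop") |>
      dplyr::mutate(category = cat, .before = 1)
  }))

  eras <- dplyr::bind_rows(lapply(names(memberships), function(cat) {
    sub <- tr[memberships[[cat]], , drop = FALSE]
    if (!nrow(sub)) return(tibble::tibble())
    sub$era <- ifelse(sub$year < era_split,
                      paste0("pre_", era_split), paste0("from_", era_split))
    sub |>
      dplyr::group_by(era = .data$era) |>
      dplyr::summarise(
        n_combos_distinct = dplyr::n_distinct(paste(.data$taxon,
                                                    .data$exporter)),
        n_combo_years = dplyr::n_distinct(paste(.data$taxon, .data$exporter,
                                                .data$year)),
        n_species = dplyr::n_distinct(.data$taxon),
        n_exporters = dplyr::n_distinct(.data$exporter),
        volume = sum(.data$quantity), .groups = "drop") |>
      dplyr::mutate(category = cat, .before = 1)
  }))
  list(cells = cells, eras = eras)
}
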