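#' Percentage of a quota used
#'
#' `100 * volume / amount` for positive quotas; undefined (`NA`) for zero
#' quotas, where any trade at all is a subversion rather than a percentage.
#' Headline figures are conventionally reported at one decimal place and
#' table cells at the nearest integer, both rounded half-up.
#'
#' @param volume Traded volume (count, >= 0). Vectorized.
#' @param amount Quota amount (count, >= 0). Vectorized.
#' @param digits Decimal places (half-up); default 1.
#' @return Numeric vector of percentages; `NA` where `amount == 0`.
#' @export
#' @examples
#' percent_use(696, 63)             # 1104.8
#' percent_use(1320, 200, digits = 0)  # 660
percent_use <- function(volume, amount, digits = 1) {
  if (any(volume < 0, na.rm = TRUE) || any(amount < 0, na.rm = TRUE))
    stop("volume and amount must be non-negative")
  ifelse(amount > 0, round_half_up(100 * volume / amount, digits), NA_real_)
}

#' Evaluate compliance of quotas against matched traded volumes
#'
#' For each quota with its exporter- and importer-reported volumes attached
#' ([build_volume_cells()]), computes percent use from both reporting
#' perspectives and the breach flags:
#' \describe{
#'   \item{breach_exporter}{positive quota strictly exceeded by the
#'     exporter-reported volume (trading exactly the quota amount is
#'     compliant);}
#'   \item{breach_importer_only}{exporter-reported volume compliant but the
#'     importer-reported volume strictly exceeds the quota — a probable
#'     hidden breach;}
#'   \item{zero_breach}{any reported trade (either perspective) under a
#'     zero quota (a ban).}
#' }
#'
#' @param quotas Quota tibble with `exporter_volume` and `importer_volume`.
#' @return Tibble of compliance results, one row per quota.
#' @export
evaluate_compliance <- function(quotas) {
  need <- c("id", "amount", "exporter_volume", "importer_volume")
  missing <- setdiff(need, names(quotas))
  if (length(missing))
    stop("quotas lack column(s): ", paste(missing, collapse = ", "))
  amt <- quotas$amount
  ev <- quotas$exporter_volume
  iv <- quotas$importer_volume
  keep <- intersect(c("id", "party", "taxon", "year", "amount",
                      "exporter_volume", "importer_volume"), names(quotas))
  out <- tibble::as_tibble(quotas[keep])
  out$pct_use_exporter <- percent_use(ev, amt)
  out$pct_use_importer <- percent_use(iv, amt)
  out$zero_breach <- amt == 0 & (ev > 0 | iv > 0)
  out$breach_exporter <- amt > 0 & ev > amt
  out$breach_importer_only <- !out$breach_exporter & amt > 0 & iv > amt
  out
}

#' Evaluate a single quota against a single volume cell
#'
#' Convenience wrapper around [evaluate_compliance()] for one quota; the
#' cell's (taxon, exporter, year) must match the quota's key.
#'
#' @param quota One-row quota tibble.
#' @param cell One-row volume tibble (`taxon`, `exporter`, `year`,
#'   `exporter_volume`, `importer_volume`).
#' @return One-row compliance tibble.
#' @export
evaluate_quota <- function(quota, cell) {
  if (!identical(unname(unlist(quota[c("taxon", "party", "year")])),
                 unname(unlist(cell[c("taxon", "exporter", "year")]))))
    stop("volume cell key does not match quota key")
  quota$exporter_volume <- cell$exporter_volume
  quota$importer_volume <- cell$importer_volume
  evaluate_compliance(quota)
}

#' Summarize compliance results
#'
#' Tallies zero and non-zero quotas and their breaches, and computes the two
#' mean percent-use statistics: over all positive quotas (quotas that were
#' never traded contribute 0%) and over traded quotas only. Undefined
#' percentages (zero quotas) are excluded from both means. Per-party breach
#' tallies are returned alongside.
#'
#' @param results Compliance tibble ([evaluate_compliance()]).
#' @param digits Decimal places for reported percentages (half-up).
#' @return List with scalar summary fields and a `per_party` tibble.
#' @export
summarize_compliance <- function(results, digits = 1) {
  zero <- results$amount == 0
  n_zero <- sum(zero)
  n_zero_breach <- sum(results$zero_breach[zero])
  nz <- results[!zero, , drop = FALSE]
  n_nonzero <- nrow(nz)
  n_breach <- sum(nz$breach_exporter)
  traded <- nz$exporter_volume > 0
  mean_all <- if (n_nonzero)
    round_half_up(mean(100 * nz$exporter_volume / nz$amount), digits)
  else NA_real_
  mean_traded <- if (any(traded))
    round_half_up(mean(100 * nz$exporter_volume[traded] / nz$amount[traded]),
                  digits)
  else NA_real_
  per_party <- if ("party" %in% names(results)) {
    results |>
      dplyr::group_by(.data$party) |>
      dplyr::summarise(
        n_quotas = dplyr::n(),
        n_breaches = sum(.data$breach_exporter),
        n_zero_breaches = sum(.data$zero_breach),
        breach_rate_pct = round_half_up(
          100 * sum(.data$breach_exporter) / max(1, sum(.data$amount > 0)),
          digits),
        .groups = "drop")
  } else tibble::tibble()
  list(
    n_zero_quotas = n_zero,
    n_zero_breaches = n_zero_breach,
    pct_zero_complied = if (n_zero)
      round_half_up(100 * (n_zero - n_zero_breach) / n_zero, digits)
    else NA_real_,
    n_nonzero_quotas = n_nonzero,
    n_nonzero_breaches = n_breach,
    pct_nonzero_breached = if (n_nonzero)
      round_half_up(100 * n_breach / n_nonzero, digits) else NA_real_,
    n_untraded = sum(!traded),
    mean_pct_use_all = mean_all,
    mean_pct_use_traded = mean_traded,
    per_party = per_party)
}

#' Probable hidden breaches: compliant exporter, breaching importer
#'
#' Rows where the exporter-reported volume was quota compliant but the
#' importer-reported volume breached the quota, plus zero quotas with
#' importer-only trade. Zero-quota rows rank first (by importer volume,
#' descending), then positive quotas by importer percent use descending,
#' ties broken by absolute excess volume and then key order. Percent cells
#' are formatted "volume (pct%)" with integer half-up percentages; zero
#' quotas show "volume (–)".
#'
#' @param results Compliance tibble.
#' @return Ranked tibble with raw and formatted columns.
#' @export
discrepancy_table <- function(results) {
  sel <- results$breach_importer_only |
    (results$amount == 0 & results$importer_volume > 0 &
       results$exporter_volume == 0)
  tab <- results[sel, , drop = FALSE]
  if (!nrow(tab)) return(tab)
  pct_i <- percent_use(tab$importer_volume, tab$amount, digits = 0)
  pct_e <- percent_use(tab$exporter_volume, tab$amount, digits = 0)
  excess <- tab$importer_volume - tab$amount
  ord <- order(-as.integer(tab$amount == 0),
               ifelse(tab$amount == 0, -tab$importer_volume, 0),
               -ifelse(is.na(pct_i), Inf, pct_i),
               -excess,
               if ("id" %in% names(tab)) tab$id else seq_len(nrow(tab)))
  tab <- tab[ord, , drop = FALSE]
  tab$pct_use_exporter <- pct_e[ord]
  tab$pct_use_importer <- pct_i[ord]
  tab$exporter_cell <- format_pct_cell(tab$exporter_volume,
                                       tab$pct_use_exporter)
  tab$importer_cell <- format_pct_cell(tab$importer_volume,
                                       tab$pct_use_importer)
  tab
}

format_pct_cell <- function(volume, pct) {
  ifelse(is.na(pct), sprintf("%d (–)", volume),
         sprintf("%d (%d%%)", volume, as.integer(pct)))
}
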