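# Shared fixture builders: everything is generated in code, no stored data.

quota_row <- function(party = "ID", year = 2005L, taxon = "Genus01 species01",
                      rank = "species", amount = 100, notes = "live") {
  tibble::tibble(party = party, year = as.integer(year), taxon = taxon,
                 rank = rank, amount = amount, notes = notes)
}

# minimal cleaned-quota record as clean_quotas() emits
quota_record <- function(id = "q00001", party = "ID", year = 2005L,
                         taxon = "Genus01 species01", rank = "species",
                         amount = 100L, terms = "live", sources = "wild",
                         purposes = "ALL", region = NA_character_) {
  tibble::tibble(
    id = id, party = party, year = as.integer(year), taxon = taxon,
    rank = rank, amount = as.integer(amount), terms = terms,
    sources = sources, purposes = purposes,
    scope = paste0("terms=", terms, ";sources=", sources,
                   ";purposes=", purposes),
    comparable = TRUE, region = region, unparsed = "",
    is_zero = amount == 0L, notes = NA_character_, provenance = "")
}

trade_record <- function(year = 2005L, taxon = "Genus01 species01",
                         exporter = "ID", importer = "XX", term = "live",
                         source = "wild", purpose = "commercial", unit = "",
                         origin = NA_character_,
                         reporter = "exporter_reported", quantity = 10L) {
  tibble::tibble(year = as.integer(year), taxon = taxon, exporter = exporter,
                 importer = importer, term = term, source = source,
                 purpose = purpose, unit = unit, origin = origin,
                 reporter = reporter, quantity = as.integer(quantity))
}

# compliance-result row without going through the ledger
result_row <- function(amount, ev = 0L, iv = ev, party = "ID",
                       id = "q00001") {
  evaluate_compliance(tibble::tibble(
    id = id, party = party, taxon = "T", year = 2005L,
    amount = as.integer(amount), exporter_volume = as.integer(ev),
    importer_volume = as.integer(iv)))
}

local_vocab <- quota_vocabulary()
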