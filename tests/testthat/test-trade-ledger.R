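test_that("live-direct filtering keeps count-unit direct live trade only", {
  recs <- dplyr::bind_rows(
    trade_record(),                                  # live, blank unit, direct
    trade_record(unit = "specimens"),
    trade_record(unit = "kg"),                       # weight: out
    trade_record(term = "skins"),                    # not live: out
    trade_record(origin = "MG"),                     # re-export: out
    trade_record(origin = "ID"))                     # origin == exporter: kept
  out <- filter_live_direct(recs)
  expect_identical(nrow(out), 3L)
  expect_true(all(out$term == "live"))
  # idempotence
  expect_identical(filter_live_direct(out), out)
})

test_that("volume aggregation equals the per-record loop oracle", {
  oracle <- function(records, terms, sources, purposes, taxon, exporter,
                     year) {
    ev <- iv <- 0
    for (i in seq_len(nrow(records))) {
      r <- records[i, ]
      if (r$taxon != taxon || r$exporter != exporter || r$year != year) next
      dim_in <- function(dim_str, val) dim_str == "ALL" ||
        val %in% strsplit(dim_str, "+", fixed = TRUE)[[1]]
      if (!dim_in(terms, r$term) || !dim_in(sources, r$source) ||
          !dim_in(purposes, r$purpose)) next
      if (r$reporter == "exporter_reported") ev <- ev + r$quantity
      else iv <- iv + r$quantity
    }
    c(ev, iv)
  }
  set.seed(99)
  for (rep in 1:20) {
    n <- 40
    recs <- tibble::tibble(
      year = sample(2005:2007, n, TRUE),
      taxon = sample(c("A a", "B b"), n, TRUE),
      exporter = sample(c("ID", "MG"), n, TRUE),
      importer = "XX",
      term = sample(c("live", "skins", "meat"), n, TRUE),
      source = sample(c("wild", "captive", "ranched"), n, TRUE),
      purpose = sample(c("commercial", "zoo"), n, TRUE),
      unit = "", origin = NA_character_,
      reporter = sample(c("exporter_reported", "importer_reported"), n,
                        TRUE),
      quantity = sample(1:100, n, TRUE))
    terms <- sample(c("ALL", "live", "live+skins"), 1)
    sources <- sample(c("ALL", "wild", "captive+wild"), 1)
    purposes <- sample(c("ALL", "commercial"), 1)
    cell <- aggregate_volumes(recs, terms, sources, purposes,
                              "A a", "ID", 2006)
    exp <- oracle(recs, terms, sources, purposes, "A a", "ID", 2006)
    expect_equal(c(cell$exporter_volume, cell$importer_volume), exp)
  }
})

test_that("widening any scope dimension never decreases volumes", {
  set.seed(5)
  n <- 60
  recs <- tibble::tibble(
    year = 2006L, taxon = "A a", exporter = "ID", importer = "XX",
    term = sample(c("live", "skins"), n, TRUE),
    source = sample(c("wild", "captive"), n, TRUE),
    purpose = sample(c("commercial", "zoo"), n, TRUE),
    unit = "", origin = NA_character_,
    reporter = sample(c("exporter_reported", "importer_reported"), n, TRUE),
    quantity = sample(1:50, n, TRUE))
  narrow <- aggregate_volumes(recs, "live", "wild", "commercial",
                              "A a", "ID", 2006)
  for (wide in list(c("ALL", "wild", "commercial"),
                    c("live", "ALL", "commercial"),
                    c("live", "wild", "ALL"),
                    c("ALL", "ALL", "ALL"))) {
    w <- aggregate_volumes(recs, wide[1], wide[2], wide[3], "A a", "ID",
                           2006)
    expect_gte(w$exporter_volume, narrow$exporter_volume)
    expect_gte(w$importer_volume, narrow$importer_volume)
  }
})

test_that("Malaysian regional quotas sum to one national quota", {
  reg <- dplyr::bind_rows(
    quota_record(id = "q1", party = "MY", amount = 10L, region = "sabah"),
    quota_record(id = "q2", party = "MY", amount = 20L, region = "sarawak"),
    quota_record(id = "q3", party = "MY", amount = 30L,
                 region = "peninsular_malaysia"))
  out <- sum_malaysian_regions(reg)
  expect_identical(nrow(out), 1L)
  expect_identical(out$amount, 60L)
  expect_identical(out$provenance, "region_summed")

  # single national quota passes through unchanged
  nat <- quota_record(party = "MY")
  expect_identical(sum_malaysian_regions(nat), nat)

  # two of three regions present: summed over those present
  out2 <- sum_malaysian_regions(reg[1:2, ])
  expect_identical(out2$amount, 30L)
  expect_identical(out2$provenance, "region_summed")
})

test_that("overlapping quota scopes are removed pairwise, disjoint kept", {
  q <- dplyr::bind_rows(
    quota_record(id = "a", terms = "live", sources = "wild"),
    quota_record(id = "b", terms = "live", sources = "ALL"),
    quota_record(id = "c", terms = "skins", sources = "wild"),
    quota_record(id = "d", party = "MG", terms = "live", sources = "ALL"))
  out <- remove_overlapping_quotas(q)
  expect_setequal(out$removed$id, c("a", "b"))
  expect_setequal(out$kept$id, c("c", "d"))
  expect_true(all(out$removed$reason == "overlapping_scope"))
})

test_that("species with live plus disjoint other-term quotas are excluded", {
  q <- dplyr::bind_rows(
    quota_record(id = "a", taxon = "Ptyas mucosus", terms = "live",
                 amount = 400L),
    quota_record(id = "b", taxon = "Ptyas mucosus", year = 2006L,
                 terms = "skins", amount = 90000L),
    quota_record(id = "c", taxon = "Other species", terms = "live"))
  out <- exclude_cross_term_species(q)
  expect_setequal(out$removed$id, c("a", "b"))
  expect_identical(out$kept$id, "c")
  # config override list
  out2 <- exclude_cross_term_species(
    q, extra_exclusions = tibble::tibble(party = "ID",
                                         taxon = "Other species"))
  expect_identical(nrow(out2$kept), 0L)
})

test_that("trade CSV round-trips through the comparative-tabulation shape", {
  cfg <- scenario_config(seed = 12, n_species = 20,
                         gaps = list(n_unmanaged_species = 4))
  qt <- gen_quota_table(cfg)
  cl <- clean_quotas(qt$rows, qt$split_events, local_vocab, warn = FALSE)
  led <- gen_trade_ledger(cfg, cl$quotas)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trade_csv(led$records, f)
  back <- read_trade_csv(f)
  key <- function(d) dplyr::arrange(
    dplyr::summarise(
      dplyr::group_by(d, .data$year, .data$taxon, .data$exporter,
                      .data$reporter),
      q = sum(.data$quantity), .groups = "drop"),
    .data$year, .data$taxon, .data$exporter, .data$reporter)
  expect_identical(key(back), key(led$records))
})

test_that("fractional specimen counts are rounded with a warning", {
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    year = 2005, taxon = "A a", term = "live", unit = "",
    importer = "XX", exporter = "ID", origin = NA, purpose = "commercial",
    source = "wild", exporter_qty = 10.4, importer_qty = NA), f)
  expect_warning(out <- read_trade_csv(f), "fractional")
  expect_identical(out$quantity, 10L)
})
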