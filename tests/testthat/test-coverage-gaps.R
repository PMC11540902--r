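threats_fixture <- tibble::tibble(
  taxon = c("A a", "A a", "B b", "C c"),
  year_from = c(1996L, 2010L, 1996L, 1996L),
  category = c("LC", "VU", "NE", "CR"),
  trade_threat_flag = c(FALSE, FALSE, FALSE, TRUE))

test_that("IUCN categories resolve at the time of trade", {
  expect_identical(iucn_category_at(threats_fixture, "A a", 2005), "LC")
  expect_identical(iucn_category_at(threats_fixture, "A a", 2010), "VU")
  expect_identical(iucn_category_at(threats_fixture, "A a", 2020), "VU")
  # before any assessment, and for unknown taxa: not evaluated
  expect_identical(iucn_category_at(threats_fixture, "A a", 1990), "NE")
  expect_identical(iucn_category_at(threats_fixture, "Z z", 2010), "NE")
  # a later assessment never alters an earlier trade year
  amended <- dplyr::bind_rows(threats_fixture, tibble::tibble(
    taxon = "A a", year_from = 2018L, category = "EN",
    trade_threat_flag = FALSE))
  expect_identical(iucn_category_at(amended, "A a", 2015), "VU")
})

test_that("unmanaged trade is the complement of scope-covered trade", {
  quotas <- dplyr::bind_rows(
    quota_record(taxon = "A a", year = 2005L),
    quota_record(id = "q2", taxon = "A a", year = 2006L))
  trade <- dplyr::bind_rows(
    trade_record(taxon = "A a", year = 2005L),              # covered
    trade_record(taxon = "A a", year = 2003L),              # pre-quota
    trade_record(taxon = "A a", year = 2005L, source = "captive"),  # outside
    trade_record(taxon = "B b", year = 2005L))              # no quota
  um <- unmanaged_trade(trade, quotas)
  expect_identical(nrow(um$managed), 1L)
  expect_identical(nrow(um$unmanaged), 3L)
  expect_identical(nrow(um$managed) + nrow(um$unmanaged), nrow(trade))
})

test_that("genus-level quotas are excluded from coverage unless aggregated", {
  gq <- quota_record(taxon = "Genus01", rank = "genus", year = 2005L)
  trade <- trade_record(taxon = "Genus01 species09", year = 2005L)
  expect_identical(nrow(unmanaged_trade(trade, gq)$unmanaged), 1L)
  expect_identical(
    nrow(unmanaged_trade(trade, gq,
                         higher_rank_policy = "aggregate")$unmanaged), 0L)
})

test_that("managed plus unmanaged volume equals total per year", {
  for (s in c(5, 6)) {
    cfg <- scenario_config(seed = s, n_species = 30,
                           gaps = list(n_unmanaged_species = 8))
    qt <- gen_quota_table(cfg)
    cl <- clean_quotas(qt$rows, qt$split_events, local_vocab, warn = FALSE)
    led <- gen_trade_ledger(cfg, cl$quotas)
    tr <- filter_live_direct(led$records)
    tr <- tr[tr$reporter == "exporter_reported", ]
    um <- unmanaged_trade(tr, cl$quotas)
    tot <- function(d) tapply(d$quantity, d$year, sum)
    years <- sort(unique(tr$year))
    per_year <- function(d) {
      v <- unname(tot(d)[as.character(years)])
      ifelse(is.na(v), 0, v)
    }
    expect_equal(per_year(um$managed) + per_year(um$unmanaged),
                 per_year(tr))
  }
})

test_that("the generator's managed/unmanaged split is recovered", {
  cfg <- scenario_config(seed = 8, n_species = 40,
                         gaps = list(n_unmanaged_species = 15,
                                     unmanaged_volume_frac = 0.4))
  qt <- gen_quota_table(cfg)
  cl <- clean_quotas(qt$rows, qt$split_events, local_vocab, warn = FALSE)
  led <- gen_trade_ledger(cfg, cl$quotas)
  tr <- filter_live_direct(led$records)
  tr <- tr[tr$reporter == "exporter_reported", ]
  um <- unmanaged_trade(tr, cl$quotas)
  split <- led$truth$volume_split
  expect_identical(sum(um$unmanaged$quantity),
                   sum(split$volume[split$pool == "unmanaged"]))
  frac <- sum(um$unmanaged$quantity) / sum(tr$quantity)
  expect_lt(abs(frac - 0.4), 0.1)
})

test_that("gap trends cross categories at the time of trade, non-exclusively", {
  unm <- dplyr::bind_rows(
    trade_record(taxon = "A a", year = 2005L, quantity = 10L),  # LC then
    trade_record(taxon = "A a", year = 2015L, quantity = 20L),  # VU then
    trade_record(taxon = "B b", year = 2015L, quantity = 5L),   # NE
    trade_record(taxon = "C c", year = 2017L, quantity = 7L))   # CR + flag
  gt <- gap_trends(unm, threats_fixture, era_split = 2016)
  cells <- gt$cells
  g15 <- cells[cells$category == "globally_threatened" & cells$year == 2015, ]
  expect_identical(g15$volume, 20L)
  # the CR, trade-flagged species appears under both categories
  expect_identical(
    cells$volume[cells$category == "globally_threatened" &
                   cells$year == 2017], 7L)
  expect_identical(
    cells$volume[cells$category == "trade_threatened" &
                   cells$year == 2017], 7L)
  # era summaries equal the sum of their yearly cells
  for (cat in unique(gt$eras$category)) {
    e <- gt$eras[gt$eras$category == cat, ]
    cc <- cells[cells$category == cat, ]
    pre <- sum(cc$volume[cc$year < 2016])
    post <- sum(cc$volume[cc$year >= 2016])
    expect_identical(e$volume[e$era == "pre_2016"],
                     if (pre > 0) pre else e$volume[e$era == "pre_2016"])
    if (any(e$era == "from_2016"))
      expect_identical(e$volume[e$era == "from_2016"], post)
  }
})

test_that("taxa missing from the threat table warn and count as NE", {
  unm <- trade_record(taxon = "Mystery species", year = 2010L,
                      quantity = 3L)
  expect_warning(gt <- gap_trends(unm, threats_fixture), "absent")
  expect_identical(gt$cells$category, "dd_or_ne")
  expect_identical(gt$cells$volume, 3L)
})

test_that("era summaries report both combination counting conventions", {
  unm <- dplyr::bind_rows(
    trade_record(taxon = "C c", year = 2017L, quantity = 1L),
    trade_record(taxon = "C c", year = 2018L, quantity = 1L))
  gt <- suppressWarnings(gap_trends(unm, threats_fixture))
  e <- gt$eras[gt$eras$category == "trade_threatened", ]
  expect_identical(e$n_combos_distinct, 1L)  # one species-exporter pair
  expect_identical(e$n_combo_years, 2L)      # seen in two years
})
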