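test_that("exact duplicates are removed, near-duplicates kept, order stable", {
  r <- quota_row()
  d <- deduplicate_quotas(dplyr::bind_rows(r, r))
  expect_identical(nrow(d$rows), 1L)
  expect_identical(nrow(d$removed), 1L)

  d <- deduplicate_quotas(dplyr::bind_rows(r, quota_row(amount = 200)))
  expect_identical(nrow(d$rows), 2L)

  # 10 rows with 2 exact duplicates -> 8 rows (brute-force set comparison)
  base <- dplyr::bind_rows(lapply(1:8, function(i)
    quota_row(year = 2000L + i, amount = i * 10)))
  rows <- dplyr::bind_rows(base, base[c(2, 5), ])
  d <- deduplicate_quotas(rows)
  expect_identical(nrow(d$rows), 8L)
  expect_identical(d$rows, rows[1:8, ])  # order stable
  # oracle: unique() agrees
  expect_identical(nrow(d$rows), nrow(unique(rows)))
})

test_that("back-dated split quotas are removed only when duplicating a parent", {
  parent <- dplyr::bind_rows(lapply(2014:2017, function(y)
    quota_row(taxon = "Cyclemys dentata", year = y, amount = 50)))
  child_dup <- parent[1:3, ]
  child_dup$taxon <- "Cyclemys enigmatica"
  child_post <- quota_row(taxon = "Cyclemys enigmatica", year = 2018L,
                          amount = 50)
  child_orphan <- quota_row(taxon = "Cyclemys enigmatica", year = 2015L,
                            amount = 999)
  events <- tibble::tibble(parent_taxon = "Cyclemys dentata",
                           child_taxon = "Cyclemys enigmatica",
                           adoption_year = 2017L)
  rows <- dplyr::bind_rows(parent, child_dup, child_post, child_orphan)
  res <- drop_backdated_split_quotas(rows, events)
  expect_identical(nrow(res$removed), 3L)
  expect_true(all(res$removed$taxon == "Cyclemys enigmatica"))
  expect_true(all(res$removed$year < 2017))
  expect_true(child_post$year %in% res$rows$year[res$rows$taxon ==
                                                  "Cyclemys enigmatica"])
  expect_identical(nrow(res$flagged_orphans), 1L)
  expect_identical(res$flagged_orphans$amount, 999)
})

test_that("split events naming absent taxa warn", {
  events <- tibble::tibble(parent_taxon = "Nohere atall",
                           child_taxon = "Nohere either",
                           adoption_year = 2015L)
  expect_warning(drop_backdated_split_quotas(quota_row(), events), "absent")
})

test_that("trinomials at species rank collapse to the binomial", {
  rows <- dplyr::bind_rows(
    quota_row(taxon = "Genus01 species01 northern", rank = "species"),
    quota_row(taxon = "Genus01 species01 northern", rank = "subspecies"),
    quota_row(taxon = "Genus01 species01", rank = "species"))
  out <- resolve_subspecies(rows)
  expect_identical(out$taxon,
                   c("Genus01 species01", "Genus01 species01 northern",
                     "Genus01 species01"))
  expect_identical(out$subspecies_resolved, c(TRUE, FALSE, FALSE))
})

test_that("invalid rows are partitioned with reasons", {
  rows <- dplyr::bind_rows(
    quota_row(amount = -1),
    quota_row(amount = NA),
    quota_row(notes = "live, March 2012 to March 2013"),
    quota_row(notes = "quota concerns re-exports only"),
    quota_row())
  f <- filter_invalid_quotas(rows)
  expect_identical(nrow(f$kept), 1L)
  expect_identical(sort(f$removed$reason),
                   c("multi_year_span", "reexport_only", "sentinel_amount",
                     "sentinel_amount"))
  expect_identical(nrow(f$kept) + nrow(f$removed), nrow(rows))
  # a within-year month span is not a multi-year span
  f2 <- filter_invalid_quotas(quota_row(notes = "March 2012 to June 2012"))
  expect_identical(nrow(f2$removed), 0L)
})

test_that("cleaning removes exactly the planted artefacts of a scenario", {
  cfg <- scenario_config(seed = 42)
  qt <- gen_quota_table(cfg)
  cl <- clean_quotas(qt$rows, qt$split_events, local_vocab, warn = FALSE)
  a <- cl$audit
  expect_identical(a$removed[a$stage == "deduplicate"],
                   qt$truth$n_duplicates)
  expect_identical(a$removed[a$stage == "split_backdated"],
                   qt$truth$n_split_backdated)
  expect_identical(a$removed[a$stage == "invalid"],
                   qt$truth$n_sentinel + qt$truth$n_multi_year +
                     qt$truth$n_reexport)
  expect_identical(nrow(cl$quotas), qt$truth$n_expected_clean)
  expect_identical(sum(cl$quotas$is_zero), qt$truth$n_zero)
  expect_identical(sum(cl$quotas$provenance == "subspecies_resolved"),
                   qt$truth$n_trinomial_at_species_rank)
  # per-stage removals sum to input minus output
  expect_identical(sum(a$removed), nrow(qt$rows) - nrow(cl$quotas))
})

test_that("the cleaning chain is idempotent", {
  cfg <- scenario_config(seed = 7)
  qt <- gen_quota_table(cfg)
  cl1 <- clean_quotas(qt$rows, qt$split_events, local_vocab, warn = FALSE)
  # feed the cleaned records back through as raw rows
  raw_again <- cl1$quotas[c("party", "year", "taxon", "rank", "amount",
                            "notes")]
  cl2 <- clean_quotas(raw_again, qt$split_events, local_vocab, warn = FALSE)
  expect_identical(nrow(cl2$quotas), nrow(cl1$quotas))
  expect_identical(sum(cl2$audit$removed), 0L)
  expect_identical(cl2$quotas$scope, cl1$quotas$scope)
})

test_that("quota CSV reader applies header maps and validates columns", {
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    Party = "MG", Year = 2010, Taxon = "Uroplatus lineatus",
    Rank = "species", Quota = 63, Notes = "live"), f)
  rows <- read_quota_csv(f, header_map = c(
    Party = "party", Year = "year", Taxon = "taxon", Rank = "rank",
    Quota = "amount", Notes = "notes"))
  expect_identical(rows$amount, 63)
  expect_identical(rows$year, 2010L)
  expect_error(read_quota_csv(f), "lacks column")
})

test_that("the audit log is written as one JSON object per line", {
  cfg <- scenario_config(seed = 3)
  qt <- gen_quota_table(cfg)
  cl <- clean_quotas(qt$rows, qt$split_events, local_vocab, warn = FALSE)
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_quota_audit(cl, f)
  lines <- readLines(f)
  expect_identical(length(lines), nrow(cl$audit))
  parsed <- lapply(lines, jsonlite::fromJSON)
  expect_identical(parsed[[1]]$stage, "input")
})
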