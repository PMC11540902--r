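test_that("identical configs give identical outputs", {
  cfg1 <- scenario_config(seed = 77, n_species = 25)
  cfg2 <- scenario_config(seed = 77, n_species = 25)
  expect_identical(gen_quota_table(cfg1), gen_quota_table(cfg2))
  q <- clean_quotas(gen_quota_table(cfg1)$rows, warn = FALSE)$quotas
  expect_identical(gen_trade_ledger(cfg1, q), gen_trade_ledger(cfg2, q))
  expect_identical(gen_prepost_series(cfg1), gen_prepost_series(cfg2))
  expect_identical(gen_update_series(cfg1), gen_update_series(cfg2))
  expect_identical(gen_threat_table(cfg1, q$taxon[1:10]),
                   gen_threat_table(cfg2, q$taxon[1:10]))
  # different seed, different world
  cfg3 <- scenario_config(seed = 78, n_species = 25)
  expect_false(identical(gen_quota_table(cfg1), gen_quota_table(cfg3)))
})

test_that("generator streams are independent of evaluation order", {
  cfg <- scenario_config(seed = 55, n_species = 20)
  pp_first <- gen_prepost_series(cfg)
  qt <- gen_quota_table(cfg)
  pp_again <- gen_prepost_series(cfg)
  expect_identical(pp_first, pp_again)
})

test_that("generated notes round-trip through the parser without warnings", {
  cfg <- scenario_config(seed = 13)
  qt <- gen_quota_table(cfg)
  cl <- clean_quotas(qt$rows, qt$split_events, local_vocab, warn = TRUE)
  expect_no_warning(
    parse_quota_notes(cl$quotas$notes, local_vocab, warn = TRUE))
  expect_true(all(cl$quotas$unparsed == ""))
})

test_that("generated files parse cleanly through the readers", {
  cfg <- scenario_config(seed = 14, n_species = 20,
                         gaps = list(n_unmanaged_species = 5))
  qt <- gen_quota_table(cfg)
  fq <- withr::local_tempfile(fileext = ".csv")
  write_quota_csv(qt$rows, fq)
  back <- read_quota_csv(fq)
  expect_identical(nrow(back), nrow(qt$rows))
  expect_no_warning(clean_quotas(back, qt$split_events, local_vocab,
                                 warn = TRUE))
  cl <- clean_quotas(back, qt$split_events, local_vocab, warn = FALSE)
  led <- gen_trade_ledger(cfg, cl$quotas)
  ft <- withr::local_tempfile(fileext = ".csv")
  write_trade_csv(led$records, ft)
  expect_no_warning(read_trade_csv(ft))
})

test_that("zero-quota share lands near its configured value", {
  cfg <- scenario_config(seed = 15, n_species = 200,
                         quotas = list(zero_share = 0.05))
  qt <- gen_quota_table(cfg)
  cl <- clean_quotas(qt$rows, qt$split_events, local_vocab, warn = FALSE)
  # zero quotas are planted per series; compare the series-level share
  zs <- tapply(cl$quotas$is_zero, cl$quotas$taxon, any)
  expect_lt(abs(mean(zs) - 0.05), 0.03)
  expect_identical(sum(cl$quotas$is_zero), qt$truth$n_zero)
})

test_that("discrepancy probability zero keeps both reporters equal", {
  cfg <- scenario_config(seed = 16, n_species = 30,
                         reporting = list(discrepancy_prob = 0),
                         compliance = list(zero_subversion_prob = 0),
                         gaps = list(n_unmanaged_species = 0))
  qt <- gen_quota_table(cfg)
  cl <- clean_quotas(qt$rows, qt$split_events, local_vocab, warn = FALSE)
  led <- gen_trade_ledger(cfg, cl$quotas)
  vols <- led$records |>
    dplyr::group_by(.data$taxon, .data$exporter, .data$year,
                    .data$reporter) |>
    dplyr::summarise(v = sum(.data$quantity), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "reporter", values_from = "v",
                       values_fill = 0L)
  expect_identical(vols$exporter_reported, vols$importer_reported)
  expect_false(any(led$truth$breaches$breach_importer_only))
})

test_that("a planted importer-only multiplier reproduces the hidden-breach pattern", {
  # quota 200 at 70% exporter use with a 6.6x importer multiple:
  # compliant exporter (140), breaching importer (1320)
  q <- quota_record(amount = 200L)
  q$exporter_volume <- 140L
  q$importer_volume <- 1320L
  r <- evaluate_compliance(q)
  expect_false(r$breach_exporter)
  expect_true(r$breach_importer_only)
  expect_identical(percent_use(r$exporter_volume, r$amount, 0), 70)
  expect_identical(percent_use(r$importer_volume, r$amount, 0), 660)
})

test_that("prepost generator honours an explicit design matrix", {
  design <- tibble::tibble(beta1 = c(1, -1), beta2 = c(1, -1),
                           beta3 = 0, beta4 = 0, beta5 = 0)
  cfg <- scenario_config(seed = 17, prepost = list(
    n_series = 4, n_pre = 5, n_post = 5, design = design, resid_sd = 0.1))
  pp <- gen_prepost_series(cfg)
  tr <- pp$truth$coefficients
  expect_equal(tr$beta1, c(1, -1, 1, -1))
  # post-quota actuals sit near the planted step for each series
  s1 <- pp$series[pp$series$taxon == tr$taxon[1] &
                    pp$series$state == "post_actual" &
                    pp$series$year_c == 0, ]
  expect_lt(abs(s1$value_std - 1), 0.5)
})

test_that("update-series generator respects hinge flatness past omega", {
  cfg <- scenario_config(seed = 18, updates = list(
    n_series = 2000, omega = 17, slope_pre = 0.3, slope_post = 0,
    length_dist = "balanced"))
  us <- gen_update_series(cfg)
  s <- us$series
  long <- s[s$length > 17, ]
  binned <- tapply(long$n_changes, long$length, mean)
  # mean changes stay near the plateau level 0.3 * 17 = 5.1 for all lengths
  expect_true(all(abs(binned - 5.1) < 0.8))
})
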