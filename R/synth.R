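#' Scenario configuration for the synthetic trade-world generator
#'
#' Bundles every knob of the synthetic quota tables, trade ledgers, threat
#' tables and model-ready series, with defaults emulating the statistical
#' structure of published reptile quota portfolios: mostly live wild-sourced
#' quotas, a ~5% share of zero quotas (bans), a ~6% breach rate with a
#' right-skewed excess distribution, heavy mass at 0% quota use with a
#' right-skewed continuous part (zero-inflated Beta), a small
#' importer-only discrepancy rate, quota-update counts generated from a
#' hinge with stagnation near 17 years, and a managed/unmanaged trade split
#' of roughly 60/40 by volume. All randomness flows from the single `seed`
#' through per-stream child seeds, so any stage can be regenerated in
#' isolation and identical configs give byte-identical outputs.
#'
#' @param seed Master integer seed.
#' @param n_parties,n_species Size of the quota world.
#' @param years Calendar-year range of the ledger.
#' @param quotas List: `zero_share`, planted artefact counts
#'   (`n_duplicates`, `n_split_backdated`, `n_sentinel`, `n_multi_year`,
#'   `n_reexport`, `n_malaysia_triplets`).
#' @param compliance List: `breach_prob`, excess-size lognormal parameters
#'   (`excess_meanlog`, `excess_sdlog`), zero-inflated-Beta use parameters
#'   (`zero_use_prob`, `use_shape1`, `use_shape2`),
#'   `zero_subversion_prob`.
#' @param reporting List: `discrepancy_prob` and lognormal multiplier
#'   parameters (`mult_meanlog`, `mult_sdlog`) for importer-only excess.
#' @param prepost List: `n_series`, `n_pre`, `n_post`, population
#'   coefficients `beta` (length 5: volume step, quota step, pre-trend,
#'   volume trend change, quota trend change), `taxon_sd`, `resid_sd`.
#' @param updates List: `n_series`, hinge truth (`omega`, `slope_pre`,
#'   `slope_post`, `intercept`).
#' @param gaps List: `n_unmanaged_species`, `unmanaged_volume_frac` (target
#'   share of total volume outside quotas), threat-category mix
#'   `category_probs` (named), `trade_threat_prob`.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(seed = 1709,
                            n_parties = 12,
                            n_species = 60,
                            years = 1997:2021,
                            quotas = list(),
                            compliance = list(),
                            reporting = list(),
                            prepost = list(),
                            updates = list(),
                            gaps = list()) {
  quotas <- utils::modifyList(list(
    zero_share = 0.05, n_duplicates = 5, n_split_backdated = 6,
    n_sentinel = 5, n_multi_year = 3, n_reexport = 2,
    n_malaysia_triplets = 2), quotas)
  compliance <- utils::modifyList(list(
    breach_prob = 0.063, excess_meanlog = -1.5, excess_sdlog = 1.2,
    zero_use_prob = 0.26, use_shape1 = 1.4, use_shape2 = 0.68,
    zero_subversion_prob = 0.045), compliance)
  reporting <- utils::modifyList(list(
    discrepancy_prob = 0.02, mult_meanlog = 0.7, mult_sdlog = 0.6),
    reporting)
  prepost <- utils::modifyList(list(
    n_series = 69, n_pre = 10, n_post = 10,
    beta = c(0, 0.9, 0, 0, 0), taxon_sd = 0.2, resid_sd = 0.3), prepost)
  updates <- utils::modifyList(list(
    n_series = 624, omega = 17, slope_pre = 0.29, slope_post = 0,
    intercept = 0, length_dist = "portfolio"), updates)
  gaps <- utils::modifyList(list(
    n_unmanaged_species = 25, unmanaged_volume_frac = 0.4,
    category_probs = c(NE = 0.25, DD = 0.15, LC = 0.3, NT = 0.1,
                       VU = 0.1, EN = 0.06, CR = 0.04),
    trade_threat_prob = 0.15), gaps)
  stopifnot(quotas$zero_share >= 0, quotas$zero_share <= 1,
            compliance$breach_prob >= 0, compliance$breach_prob <= 1,
            reporting$discrepancy_prob >= 0, reporting$discrepancy_prob <= 1,
            length(prepost$beta) == 5)
  structure(list(seed = as.integer(seed), n_parties = n_parties,
                 n_species = n_species, years = years, quotas = quotas,
                 compliance = compliance, reporting = reporting,
                 prepost = prepost, updates = updates, gaps = gaps),
            class = "scenario_config")
}

synth_party <- function(i) sprintf("P%02d", i)
synth_species <- function(i) sprintf("Genus%02d species%02d",
                                     (i - 1) %/% 10 + 1, i)

#' Generate a raw quota table with planted cleaning artefacts
#'
#' Builds multi-year quota series for synthetic species (notes drawn from
#' the controlled vocabulary grammar, a configurable share of zero quotas)
#' and then plants, with exact bookkeeping: exact duplicate rows, back-dated
#' split-taxon duplicates (with the matching split-event table), sentinel
#' amounts (-1/NA), multi-year-span notes, re-export-only notes, and
#' Malaysian-style regional triplets. The truth sidecar records every
#' planted count so ingest removals can be checked exactly.
#'
#' @param cfg A [scenario_config()].
#' @return List: `rows` (raw quota tibble for [clean_quotas()]),
#'   `split_events`, `truth`.
#' @export
gen_quota_table <- function(cfg) {
  set.seed(child_seed(cfg$seed, "quotas"))
  qc <- cfg$quotas
  notes_pool <- c(NA, "live", "live", "live", "live, wild",
                  "live, wild-taken", "all", "all, live",
                  "live, commercial", "wild", "skins", "skins and meat",
                  "live, ranched")
  rows <- list()
  for (s in seq_len(cfg$n_species)) {
    party <- synth_party((s - 1) %% cfg$n_parties + 1)
    start <- sample(cfg$years[2:(length(cfg$years) - 6)], 1)
    len <- sample(5:15, 1)
    yrs <- seq(start, min(start + len - 1, max(cfg$years)))
    note <- sample(notes_pool, 1)
    zero <- stats::runif(1) < qc$zero_share
    base <- if (zero) 0L else as.integer(round(stats::rlnorm(1, 5.5, 1)))
    amounts <- base
    for (k in seq_along(yrs)[-1]) {
      amounts[k] <- if (!zero && stats::runif(1) < 0.3)
        as.integer(max(1, round(amounts[k - 1] * stats::runif(1, 0.6, 1.5))))
      else amounts[k - 1]
    }
    rows[[s]] <- tibble::tibble(party = party, year = yrs,
                                taxon = synth_species(s), rank = "species",
                                amount = as.numeric(amounts), notes = note)
  }
  base_tbl <- dplyr::bind_rows(rows)

  # trinomial recorded at species rank (subspecies_resolved cases)
  n_tri <- 2L
  tri_idx <- match(sample(unique(base_tbl$taxon), n_tri), base_tbl$taxon)
  tri_rows <- base_tbl[tri_idx, ]
  tri_rows$taxon <- paste(tri_rows$taxon, "orientalis")
  tri_rows$year <- max(cfg$years) + 2L  # unique (avoid clashing series years)
  base_tbl <- dplyr::bind_rows(base_tbl, tri_rows)

  # exact duplicates
  dup_rows <- base_tbl[sample(nrow(base_tbl), qc$n_duplicates), ]

  # back-dated split duplicates: child taxa inherit pre-adoption rows
  n_parents <- max(1L, qc$n_split_backdated %/% 3L)
  parents <- sample(unique(base_tbl$taxon[base_tbl$rank == "species"]),
                    n_parents)
  split_events <- list()
  split_rows <- list()
  remaining <- qc$n_split_backdated
  for (p in parents) {
    prows <- base_tbl[base_tbl$taxon == p, ]
    adoption <- max(prows$year) + 1L
    take <- min(remaining, nrow(prows))
    child <- sub("species", "neospecies", p)
    ch <- prows[seq_len(take), ]
    ch$taxon <- child
    split_rows[[length(split_rows) + 1]] <- ch
    split_events[[length(split_events) + 1]] <- tibble::tibble(
      parent_taxon = p, child_taxon = child, adoption_year = adoption)
    remaining <- remaining - take
    if (remaining <= 0) break
  }
  split_rows <- dplyr::bind_rows(split_rows)
  split_events <- dplyr::bind_rows(split_events)

  # sentinel amounts, multi-year spans, re-export-only rows
  mk_extra <- function(n, amount, note) {
    if (n == 0) return(tibble::tibble())
    # distinct taxa so no planted extra can collide into an exact duplicate
    tibble::tibble(party = synth_party(sample(cfg$n_parties, n, TRUE)),
                   year = sample(cfg$years, n, replace = FALSE),
                   taxon = synth_species(sample(cfg$n_species, n,
                                                replace = FALSE)),
                   rank = "species", amount = amount, notes = note)
  }
  sentinel_rows <- mk_extra(qc$n_sentinel,
                            c(-1, NA)[1 + seq_len(qc$n_sentinel) %% 2], "live")
  span_rows <- mk_extra(qc$n_multi_year, 500,
                        "live, March 2012 to March 2013")
  reexport_rows <- mk_extra(qc$n_reexport, 200, "re-exports only")

  # Malaysian regional triplets
  my_rows <- list()
  for (m in seq_len(qc$n_malaysia_triplets)) {
    taxon <- sprintf("Malaygenus species%02d", m)
    yr <- sample(cfg$years, 1)
    amt <- as.integer(round(stats::rlnorm(3, 4, 0.5)))
    my_rows[[m]] <- tibble::tibble(
      party = "MY", year = yr, taxon = taxon, rank = "species",
      amount = as.numeric(amt),
      notes = paste0("live, ", c("sabah", "sarawak", "peninsular malaysia")))
  }
  my_rows <- dplyr::bind_rows(my_rows)

  tbl <- dplyr::bind_rows(base_tbl, dup_rows, split_rows, sentinel_rows,
                          span_rows, reexport_rows, my_rows)
  tbl <- tbl[sample(nrow(tbl)), ]  # shuffle: removal must not rely on order

  truth <- list(
    n_base = nrow(base_tbl) + nrow(my_rows),
    n_duplicates = nrow(dup_rows),
    n_split_backdated = nrow(split_rows),
    n_sentinel = nrow(sentinel_rows),
    n_multi_year = nrow(span_rows),
    n_reexport = nrow(reexport_rows),
    n_trinomial_at_species_rank = n_tri,
    n_zero = sum(base_tbl$amount == 0, na.rm = TRUE),
    malaysia_taxa = unique(my_rows$taxon),
    n_expected_clean = nrow(base_tbl) + nrow(my_rows))
  list(rows = tbl, split_events = split_events, truth = truth)
}

#' Generate a trade ledger against cleaned quotas, with known breaches
#'
#' For every positive, live-covering, comparable quota: draws a
#' fraction-of-quota use from a zero-inflated Beta (point mass at 0 plus a
#' right-skewed continuous part, mirroring the empirical use distribution);
#' with the configured breach probability the exporter-reported volume
#' instead exceeds the quota by a lognormal excess. Importer-reported
#' volumes equal exporter volumes except under the discrepancy model, where
#' (for a compliant exporter volume) the importer reports a multiple of the
#' quota. Zero quotas are subverted with the configured probability. Every
#' planted breach, importer-only breach and subversion is listed in the
#' truth sidecar keyed by quota id. Unmanaged trade for coverage analysis is
#' generated for extra species without quotas, with volumes targeting the
#' configured unmanaged share.
#'
#' @param cfg A [scenario_config()].
#' @param quotas Cleaned quota tibble ([clean_quotas()]).
#' @return List: `records` (long trade tibble as from [read_trade_csv()]),
#'   `truth` (per-quota tibble `breaches` + `unmanaged_taxa` +
#'   yearly `volume_split`).
#' @export
gen_trade_ledger <- function(cfg, quotas) {
  set.seed(child_seed(cfg$seed, "ledger"))
  cc <- cfg$compliance
  rp <- cfg$reporting
  recs <- list()
  truth_rows <- list()
  live_ok <- vapply(quotas$terms, function(t)
    identical(t, "ALL") || "live" %in% dim_unstring(t), logical(1))
  usable <- quotas[live_ok & quotas$comparable, , drop = FALSE]
  for (i in seq_len(nrow(usable))) {
    q <- usable[i, ]
    src <- if (identical(q$sources, "ALL")) "wild" else
      dim_unstring(q$sources)[1]
    pur <- if (identical(q$purposes, "ALL")) "commercial" else
      dim_unstring(q$purposes)[1]
    ev <- iv <- 0L
    breach <- FALSE; imp_only <- FALSE; subverted <- FALSE
    if (q$amount == 0) {
      if (stats::runif(1) < cc$zero_subversion_prob) {
        subverted <- TRUE
        v <- 1L + stats::rpois(1, 10)
        if (stats::runif(1) < 0.5) ev <- v else iv <- v
        if (ev > 0) iv <- ev
      }
    } else if (stats::runif(1) < cc$breach_prob) {
      breach <- TRUE
      excess <- stats::rlnorm(1, cc$excess_meanlog, cc$excess_sdlog)
      ev <- q$amount + max(1L, as.integer(round(excess * q$amount)))
      iv <- ev
    } else {
      u <- if (stats::runif(1) < cc$zero_use_prob) 0 else
        stats::rbeta(1, cc$use_shape1, cc$use_shape2)
      ev <- min(q$amount, as.integer(round(u * q$amount)))
      iv <- ev
      if (stats::runif(1) < rp$discrepancy_prob) {
        imp_only <- TRUE
        mult <- 1 + stats::rlnorm(1, rp$mult_meanlog, rp$mult_sdlog)
        iv <- q$amount + max(1L, as.integer(round((mult - 1) * q$amount)))
      }
    }
    if (ev > 0 || iv > 0) {
      recs[[length(recs) + 1]] <- split_shipments(
        q$taxon, q$party, q$year, "live", src, pur, ev, iv)
    }
    truth_rows[[length(truth_rows) + 1]] <- tibble::tibble(
      id = q$id, amount = q$amount, exporter_volume = ev,
      importer_volume = iv, breach_exporter = breach,
      breach_importer_only = imp_only, zero_breach = subverted)
  }
  managed <- if (length(recs)) dplyr::bind_rows(recs) else tibble::tibble()

  # unmanaged species (no quotas anywhere): coverage-gap fodder
  g <- cfg$gaps
  managed_total <- if (nrow(managed))
    sum(managed$quantity[managed$reporter == "exporter_reported"]) else 0
  target_unmanaged <- managed_total * g$unmanaged_volume_frac /
    max(1e-9, 1 - g$unmanaged_volume_frac)
  un <- list()
  if (g$n_unmanaged_species > 0 && target_unmanaged > 0) {
    w <- stats::rlnorm(g$n_unmanaged_species, 0, 1)
    per_sp <- target_unmanaged * w / sum(w)
    for (s in seq_len(g$n_unmanaged_species)) {
      taxon <- sprintf("Freegenus species%02d", s)
      n_yr <- sample(3:10, 1)
      yrs <- sort(sample(cfg$years, n_yr))
      vols <- as.integer(round(per_sp[s] * stats::runif(n_yr) /
                                 sum(stats::runif(n_yr)) + 1))
      vols <- pmax(vols, 1L)
      party <- synth_party(sample(cfg$n_parties, 1))
      for (k in seq_along(yrs)) {
        un[[length(un) + 1]] <- split_shipments(
          taxon, party, yrs[k], "live", "wild", "commercial",
          vols[k], vols[k])
      }
    }
  }
  unmanaged <- if (length(un)) dplyr::bind_rows(un) else tibble::tibble()
  records <- dplyr::bind_rows(managed, unmanaged)

  exp_rec <- function(d) if (!nrow(d)) tibble::tibble() else
    d[d$reporter == "exporter_reported", ]
  split_vol <- dplyr::bind_rows(
    if (nrow(managed)) dplyr::mutate(
      dplyr::summarise(dplyr::group_by(exp_rec(managed), .data$year),
                       volume = sum(.data$quantity), .groups = "drop"),
      pool = "managed"),
    if (nrow(unmanaged)) dplyr::mutate(
      dplyr::summarise(dplyr::group_by(exp_rec(unmanaged), .data$year),
                       volume = sum(.data$quantity), .groups = "drop"),
      pool = "unmanaged"))
  list(records = records,
       truth = list(breaches = dplyr::bind_rows(truth_rows),
                    unmanaged_taxa = if (nrow(unmanaged))
                      unique(unmanaged$taxon) else character(),
                    volume_split = split_vol))
}

# one shipment bundle -> 1-3 aligned exporter/importer record pairs
split_shipments <- function(taxon, exporter, year, term, source, purpose,
                            ev, iv) {
  k <- sample(1:3, 1)
  cut <- sort(stats::runif(k - 1))
  shares <- diff(c(0, cut, 1))
  ev_parts <- integer_shares(ev, shares)
  iv_parts <- integer_shares(iv, shares)
  both <- tibble::tibble(
    year = year, taxon = taxon, exporter = exporter,
    importer = "XX", term = term, source = source, purpose = purpose,
    unit = "", origin = NA_character_,
    reporter = rep(c("exporter_reported", "importer_reported"), each = k),
    quantity = c(ev_parts, iv_parts))
  both[both$quantity > 0, , drop = FALSE]
}

integer_shares <- function(total, shares) {
  if (total <= 0) return(rep(0L, length(shares)))
  parts <- floor(total * shares)
  rem <- total - sum(parts)
  if (rem > 0) parts[seq_len(rem)] <- parts[seq_len(rem)] + 1
  as.integer(parts)
}

#' Generate a per-species threat table
#'
#' Each taxon gets an initial NE state and, usually, one later assessment
#' drawn from the configured category mix; the trade-threat flag is an
#' independent Bernoulli draw.
#'
#' @param cfg A [scenario_config()].
#' @param taxa Character vector of taxa to cover.
#' @return Tibble: `taxon`, `year_from`, `category`, `trade_threat_flag`.
#' @export
gen_threat_table <- function(cfg, taxa) {
  set.seed(child_seed(cfg$seed, "threats"))
  g <- cfg$gaps
  rows <- lapply(taxa, function(tx) {
    flag <- stats::runif(1) < g$trade_threat_prob
    base <- tibble::tibble(taxon = tx, year_from = min(cfg$years) - 1,
                           category = "NE", trade_threat_flag = flag)
    if (stats::runif(1) < 0.8) {
      cat <- sample(names(g$category_probs), 1, prob = g$category_probs)
      if (cat != "NE")
        base <- dplyr::bind_rows(base, tibble::tibble(
          taxon = tx,
          year_from = sample(seq(min(cfg$years) + 3, max(cfg$years) - 2), 1),
          category = cat, trade_threat_flag = flag))
    }
    base
  })
  dplyr::bind_rows(rows)
}

#' Generate pre/post-quota series with known coefficient truth
#'
#' Per-series coefficients are drawn around the population values in
#' `cfg$prepost$beta` with taxon s.d. `taxon_sd`; standardized values follow
#' the counterfactual model mean plus normal residuals. Returns both the
#' model-ready long table (exactly what [fit_prepost()] consumes, for
#' parameter-recovery studies where the truth must live on the model scale)
#' and a raw trade/quota table per series (volumes de-standardized with a
#' random centre and scale) for exercising [build_prepost_series()].
#'
#' @param cfg A [scenario_config()].
#' @return List: `series` (model-ready long tibble), `raw` (tibble `taxon`,
#'   `exporter`, `year`, `volume`, `quota`), `truth` (population `beta`,
#'   per-series coefficient tibble, `resid_sd`).
#' @export
gen_prepost_series <- function(cfg) {
  set.seed(child_seed(cfg$seed, "prepost"))
  pp <- cfg$prepost
  n <- pp$n_series
  if (!is.null(pp$design)) {
    # explicit per-series coefficient design (recycled to n_series):
    # used when each series must plant a known trajectory shape
    d <- as.matrix(pp$design[c("beta1", "beta2", "beta3", "beta4", "beta5")])
    b <- d[rep_len(seq_len(nrow(d)), n), , drop = FALSE]
    dimnames(b) <- NULL
  } else {
    b <- matrix(stats::rnorm(5 * n, mean = rep(pp$beta, each = n),
                             sd = pp$taxon_sd), nrow = n)
  }
  rows <- list(); raw <- list(); coef_rows <- list()
  for (s in seq_len(n)) {
    # staggered quota establishment years: calendar-year shocks are only
    # separable from the post-quota states when series start at different
    # times
    year0 <- sample(seq(min(cfg$years) + pp$n_pre,
                        max(cfg$years) - pp$n_post + 1), 1)
    taxon <- sprintf("PPgenus species%02d", s)
    exporter <- synth_party((s - 1) %% cfg$n_parties + 1)
    t_pre <- seq(-pp$n_pre, -1)
    t_post <- seq(0, pp$n_post - 1)
    y_pre <- b[s, 3] * t_pre + stats::rnorm(pp$n_pre, 0, pp$resid_sd)
    y_act <- b[s, 1] + (b[s, 3] + b[s, 4]) * t_post +
      stats::rnorm(pp$n_post, 0, pp$resid_sd)
    y_quo <- b[s, 2] + (b[s, 3] + b[s, 5]) * t_post +
      stats::rnorm(pp$n_post, 0, pp$resid_sd)
    centre <- round(stats::rlnorm(1, 6, 1))
    scale <- round(centre * stats::runif(1, 0.2, 0.6)) + 1
    mk <- function(state, t, y) tibble::tibble(
      series_id = paste(taxon, exporter, sep = ":"), taxon = taxon,
      exporter = exporter, calendar_year = year0 + t, year_c = t,
      state = state, value_std = y, value_raw = centre + scale * y,
      centre = centre, scale = scale)
    rows[[s]] <- dplyr::bind_rows(mk("pre", t_pre, y_pre),
                                  mk("post_actual", t_post, y_act),
                                  mk("post_quota", t_post, y_quo))
    raw[[s]] <- tibble::tibble(
      taxon = taxon, exporter = exporter,
      year = year0 + c(t_pre, t_post),
      volume = round(centre + scale * c(y_pre, y_act)),
      quota = c(rep(NA_real_, pp$n_pre), round(centre + scale * y_quo)))
    coef_rows[[s]] <- tibble::tibble(taxon = taxon, exporter = exporter,
                                     beta1 = b[s, 1], beta2 = b[s, 2],
                                     beta3 = b[s, 3], beta4 = b[s, 4],
                                     beta5 = b[s, 5])
  }
  list(series = dplyr::bind_rows(rows), raw = dplyr::bind_rows(raw),
       truth = list(beta = pp$beta, coefficients = dplyr::bind_rows(coef_rows),
                    resid_sd = pp$resid_sd))
}

#' Generate quota-update series with known hinge truth
#'
#' Series lengths are drawn across the feasible 2-27-year range: the
#' default `length_dist = "portfolio"` mimics real quota portfolios, which
#' are heavily weighted towards short series; `"balanced"` draws lengths
#' uniformly, the conventional design for parameter-recovery studies (a
#' short-heavy mix leaves few series beyond the stagnation point, making
#' the change point itself poorly informed). The expected number of updates
#' follows the configured hinge and realized counts use binomial thinning
#' around it (counts stay integer and within
#' [0, length - 1], which a normal-error model only approximates). Also
#' emits synthetic quota records realizing each series (amount sequences
#' with exactly the drawn number of changes, one scope per series) so the
#' counting path can be cross-checked end to end.
#'
#' @param cfg A [scenario_config()].
#' @return List: `series` (tibble as [build_update_series()] returns),
#'   `quotas` (quota-record tibble realizing the series), `truth` (hinge
#'   parameters and per-series expected/realized counts).
#' @export
gen_update_series <- function(cfg) {
  set.seed(child_seed(cfg$seed, "updates"))
  up <- cfg$updates
  lens <- if (identical(up$length_dist, "balanced"))
    sample(2:27, up$n_series, replace = TRUE)
  else pmin(27L, 2L + stats::rgeom(up$n_series, 0.12))
  rows <- list(); qrows <- list()
  for (s in seq_len(up$n_series)) {
    L <- lens[s]
    mu <- up$intercept + up$slope_pre * min(L, up$omega) +
      up$slope_post * max(L - up$omega, 0)
    p <- min(1, max(0, mu / (L - 1)))
    nc <- stats::rbinom(1, L - 1, p)
    taxon <- sprintf("UPgenus species%03d", s)
    party <- synth_party((s - 1) %% cfg$n_parties + 1)
    start <- sample(seq(1997, 2023 - L + 1), 1)
    amounts <- rep(100L + s, L)
    if (nc > 0) {
      yrs_idx <- seq(2L, L)
      change_at <- sort(yrs_idx[sample.int(length(yrs_idx), nc)])
      val <- amounts[1]
      for (k in 2:L) {
        if (k %in% change_at) val <- val + sample(c(-30L, -10L, 10L, 30L), 1)
        amounts[k] <- val
      }
    }
    rows[[s]] <- tibble::tibble(taxon = taxon, party = party,
                                scope = "terms=live;sources=wild;purposes=ALL",
                                start_year = start, length = L,
                                n_changes = nc, contains_zero_quota = FALSE)
    qrows[[s]] <- tibble::tibble(
      id = sprintf("u%04d-%02d", s, seq_len(L)), party = party,
      year = seq(start, start + L - 1), taxon = taxon, rank = "species",
      amount = amounts, terms = "live", sources = "wild", purposes = "ALL",
      scope = "terms=live;sources=wild;purposes=ALL", comparable = TRUE,
      region = NA_character_, unparsed = "", is_zero = FALSE,
      notes = "live", provenance = "")
  }
  series <- dplyr::bind_rows(rows)
  list(series = series, quotas = dplyr::bind_rows(qrows),
       truth = list(omega = up$omega, slope_pre = up$slope_pre,
                    slope_post = up$slope_post, intercept = up$intercept,
                    series = series))
}

#' Write synthetic tables in the CSV dialects the readers consume
#'
#' @param rows Raw quota tibble ([gen_quota_table()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_quota_csv <- function(rows, path) {
  readr::write_csv(rows, path, na = "")
  invisible(path)
}

#' @rdname write_quota_csv
#' @param records Long trade-record tibble ([gen_trade_ledger()]); written
#'   wide (one row per shipment key with exporter/importer quantity
#'   columns), the comparative-tabulation shape [read_trade_csv()] expects.
#' @export
write_trade_csv <- function(records, path) {
  key <- c("year", "taxon", "exporter", "importer", "term", "source",
           "purpose", "unit", "origin")
  records <- records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(key, "reporter")))) |>
    dplyr::mutate(row = dplyr::row_number()) |>
    dplyr::ungroup()
  wide <- tidyr::pivot_wider(records, id_cols = dplyr::all_of(c(key, "row")),
                             names_from = "reporter",
                             values_from = "quantity")
  wide$row <- NULL
  names(wide)[names(wide) == "exporter_reported"] <- "exporter_qty"
  names(wide)[names(wide) == "importer_reported"] <- "importer_qty"
  if (!"exporter_qty" %in% names(wide)) wide$exporter_qty <- NA_integer_
  if (!"importer_qty" %in% names(wide)) wide$importer_qty <- NA_integer_
  readr::write_csv(wide, path, na = "")
  invisible(path)
}
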