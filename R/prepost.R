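#' Build standardized pre/post-quota series
#'
#' Turns per-year trade and quota levels into the long model table for the
#' counterfactual fit. Input is one row per (taxon, exporter, year) with the
#' actual traded `volume` and the `quota` level (`NA` in years with no
#' quota). For each taxon-exporter combination the first quota year defines
#' year 0; series are kept only when they have at least `min_pre` observed
#' pre-quota years and `min_post` quota years, and (when a membership table
#' is supplied) the party/taxon was eligible at least `min_pre` years before
#' the first quota.
#'
#' Volumes are zero-centred on the last pre-quota year and scaled by the
#' series' own volume standard deviation (group-level standardization —
#' between-series volume variance is orders of magnitude wide, and a common
#' scale would swamp small series). Quota levels are standardized with the
#' same centre and scale so that quota-level and volume contrasts share
#' units. Series with zero volume s.d. are excluded with an audit reason
#' (their standardized scale is undefined).
#'
#' Each post-quota year contributes two rows: the actual traded volume
#' (state `post_actual`) and the quota level (state `post_quota`); pre-quota
#' years contribute their volume (state `pre`).
#'
#' @param trade_series Tibble: `taxon`, `exporter`, `year`, `volume`,
#'   `quota` (`NA` = no quota that year).
#' @param membership Optional tibble `party`, `taxon`, `eligible_from`
#'   (first year the exporter/taxon pair was a signatory and listed).
#' @param min_pre,min_post Minimum pre-quota and quota years; default 5.
#' @return List with `series` (long model tibble: `series_id`, `taxon`,
#'   `exporter`, `calendar_year`, `year_c`, `state`, `value_raw`,
#'   `value_std`, `centre`, `scale`) and `excluded` (tibble of series keys
#'   with reasons).
#' @export
build_prepost_series <- function(trade_series, membership = NULL,
                                 min_pre = 5, min_post = 5) {
  groups <- split(trade_series,
                  paste(trade_series$taxon, trade_series$exporter,
                        sep = "\r"))
  out <- list()
  excluded <- list()
  for (g in groups) {
    g <- g[order(g$year), , drop = FALSE]
    key <- tibble::tibble(taxon = g$taxon[1], exporter = g$exporter[1])
    qyears <- g$year[!is.na(g$quota)]
    if (!length(qyears)) {
      excluded[[length(excluded) + 1]] <-
        cbind(key, reason = "no_quota"); next
    }
    y0 <- min(qyears)
    pre <- g[g$year < y0, , drop = FALSE]
    post <- g[g$year >= y0 & !is.na(g$quota), , drop = FALSE]
    if (nrow(pre) < min_pre || nrow(post) < min_post) {
      excluded[[length(excluded) + 1]] <-
        cbind(key, reason = "too_short"); next
    }
    if (!is.null(membership)) {
      m <- membership[membership$party == key$exporter &
                        membership$taxon == key$taxon, , drop = FALSE]
      if (nrow(m) == 0 || y0 - m$eligible_from[1] < min_pre) {
        excluded[[length(excluded) + 1]] <-
          cbind(key, reason = "not_eligible"); next
      }
    }
    centre <- pre$volume[nrow(pre)]
    scale <- stats::sd(c(pre$volume, post$volume))
    if (!is.finite(scale) || scale == 0) {
      excluded[[length(excluded) + 1]] <-
        cbind(key, reason = "zero_sd"); next
    }
    sid <- paste(key$taxon, key$exporter, sep = ":")
    rows <- dplyr::bind_rows(
      tibble::tibble(state = "pre", calendar_year = pre$year,
                     value_raw = pre$volume),
      tibble::tibble(state = "post_actual", calendar_year = post$year,
                     value_raw = post$volume),
      tibble::tibble(state = "post_quota", calendar_year = post$year,
                     value_raw = post$quota))
    rows$series_id <- sid
    rows$taxon <- key$taxon
    rows$exporter <- key$exporter
    rows$year_c <- rows$calendar_year - y0
    rows$centre <- centre
    rows$scale <- scale
    rows$value_std <- (rows$value_raw - centre) / scale
    out[[length(out) + 1]] <- rows
  }
  series <- if (length(out)) dplyr::bind_rows(out) else tibble::tibble()
  excl <- if (length(excluded)) dplyr::bind_rows(excluded) else
    tibble::tibble(taxon = character(), exporter = character(),
                   reason = character())
  list(series = series, excluded = excl)
}

prepost_jags_model <- "
model {
  for (i in 1:N) {
    y[i] ~ dnorm(mu[i], tau_res)
    mu[i] <- a0 + a_tax[tax[i]] + a_exp[expo[i]] + a_yr[yr[i]]
             + b[tax[i],1] * s_act[i]
             + b[tax[i],2] * s_quo[i]
             + b[tax[i],3] * year[i]
             + b[tax[i],4] * s_act[i] * year[i]
             + b[tax[i],5] * s_quo[i] * year[i]
  }
  for (j in 1:J) {
    for (m in 1:5) { b[j,m] ~ dnorm(mu_b[m], tau_b[m]) }
    a_tax[j] ~ dnorm(0, tau_tax)
  }
  for (k in 1:K) { a_exp[k] ~ dnorm(0, tau_exp) }
  for (l in 1:L) { a_yr[l] ~ dnorm(0, tau_yr) }
  for (m in 1:5) {
    mu_b[m] ~ dnorm(0, prec_fix)
    sd_b[m] ~ dnorm(0, prec_sd) T(0,)
    tau_b[m] <- pow(sd_b[m], -2)
  }
  a0 ~ dnorm(0, prec_fix)
  sd_tax ~ dnorm(0, prec_sd) T(0,)
  sd_exp ~ dnorm(0, prec_sd) T(0,)
  sd_yr ~ dnorm(0, prec_sd) T(0,)
  tau_tax <- pow(sd_tax, -2)
  tau_exp <- pow(sd_exp, -2)
  tau_yr <- pow(sd_yr, -2)
  sigma ~ dnorm(0, prec_sd) T(0,)
  tau_res <- pow(sigma, -2)
  # identified overall intercept: the raw a0 trades off freely against the
  # group-mean components, so convergence is assessed on this combination
  a0c <- a0 + mean(a_tax[]) + mean(a_exp[]) + mean(a_yr[])
}"

#' Fit the hierarchical pre/post-quota counterfactual model
#'
#' Gaussian hierarchical regression of standardized volume on the two
#' post-quota state indicators and the centred year:
#' \deqn{y_i \sim N(\mu_i, \sigma^2)}
#' \deqn{\mu_i = \alpha_{j[i],k[i],l[i]} + \beta_{1j}\,S^{act}_i +
#'   \beta_{2j}\,S^{quo}_i + \beta_{3j}\,t_i + \beta_{4j}\,S^{act}_i t_i +
#'   \beta_{5j}\,S^{quo}_i t_i}
#' where \eqn{S^{act}} flags post-quota actual-volume rows, \eqn{S^{quo}}
#' flags quota-level rows, and \eqn{t} is the year centred on quota
#' establishment. \eqn{\beta_1} is the counterfactual step of post-quota
#' volumes over the extrapolated pre-quota trend at year 0, \eqn{\beta_2}
#' the same for quota levels, \eqn{\beta_3} the pre-quota trend, and
#' \eqn{\beta_4}/\eqn{\beta_5} the post-quota trend changes. All five
#' coefficients vary by taxon around population means; the intercept has
#' crossed varying components for taxon, exporter and calendar year (the
#' latter absorbs year-specific shocks common across series). Priors are
#' zero-centred and diffuse: normal(0, 2.5) on the standardized scale for
#' population-level effects, half-normal(0, 2) for group and residual
#' standard deviations.
#'
#' @param series Long series tibble from [build_prepost_series()]
#'   (`$series`).
#' @param chains,warmup,sampling,thin MCMC settings; defaults 4 chains,
#'   500 warmup and 500 sampling iterations, no thinning. The defaults are
#'   quick-look settings; Gibbs sampling mixes more slowly per iteration
#'   than gradient-based samplers on this posterior, so final inference
#'   (and anything gated on the convergence diagnostic) should run longer,
#'   e.g. `warmup = 4000, sampling = 4000, thin = 4`.
#' @param seed Integer seed driving all chains.
#' @param prior_sd_fixed,prior_sd_group Prior scales for fixed effects and
#'   group/residual s.d.s.
#' @param rhat_limit Convergence limit on the potential scale reduction
#'   factor; fits at or above it are flagged unconverged. Default 1.02.
#' @return A `prepost_fit` list: `draws` (named matrix, merged chains),
#'   `taxon_draws` (list of per-taxon coefficient matrices), `summary`
#'   (population-level coefficient tibble), `taxa`, `rhat_max`, `converged`,
#'   `settings`.
#' @export
fit_prepost <- function(series, chains = 4, warmup = 500, sampling = 500,
                        seed = 1, thin = 1, prior_sd_fixed = 2.5,
                        prior_sd_group = 2, rhat_limit = 1.02) {
  stopifnot(nrow(series) > 0)
  if (length(unique(series$series_id)) < 2)
    stop("need at least 2 series to fit the hierarchical model")
  tax <- factor(series$taxon)
  expf <- factor(series$exporter)
  yrf <- factor(series$calendar_year)
  data <- list(
    N = nrow(series), y = series$value_std,
    s_act = as.numeric(series$state == "post_actual"),
    s_quo = as.numeric(series$state == "post_quota"),
    year = series$year_c,
    tax = as.integer(tax), J = nlevels(tax),
    expo = as.integer(expf), K = nlevels(expf),
    yr = as.integer(yrf), L = nlevels(yrf),
    prec_fix = 1 / prior_sd_fixed^2, prec_sd = 1 / prior_sd_group^2)
  inits <- lapply(seq_len(chains), function(c)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (seed * 1000L + c) %% 2147483587L))
  jm <- rjags::jags.model(textConnection(prepost_jags_model), data = data,
                          inits = inits, n.chains = chains, quiet = TRUE)
  stats::update(jm, warmup, progress.bar = "none")
  monitors <- c("mu_b", "b", "a0c", "sigma", "sd_b")
  samp <- rjags::coda.samples(jm, monitors, sampling * thin, thin = thin,
                              progress.bar = "none")
  draws <- as.matrix(samp)
  rhat <- max_rhat(samp[, c(paste0("mu_b[", 1:5, "]"), "a0c", "sigma")])

  pop <- dplyr::bind_rows(lapply(1:5, function(m)
    summarize_coefficient(draws[, paste0("mu_b[", m, "]")])))
  pop <- dplyr::bind_cols(tibble::tibble(coef = paste0("beta", 1:5)), pop)

  taxa <- levels(tax)
  taxon_draws <- lapply(seq_along(taxa), function(j)
    draws[, paste0("b[", j, ",", 1:5, "]"), drop = FALSE])
  names(taxon_draws) <- taxa

  structure(list(draws = draws, taxon_draws = taxon_draws, summary = pop,
                 taxa = taxa, rhat_max = rhat,
                 converged = is.finite(rhat) && rhat < rhat_limit,
                 settings = list(chains = chains, warmup = warmup,
                                 sampling = sampling, thin = thin,
                                 seed = seed)),
            class = "prepost_fit")
}

#' @export
print.prepost_fit <- function(x, ...) {
  cat("Hierarchical pre/post-quota counterfactual fit\n")
  cat(sprintf("  %d taxa; %d chains x %d sampling draws; max Rhat %.3f%s\n",
              length(x$taxa), x$settings$chains, x$settings$sampling,
              x$rhat_max, if (x$converged) "" else " (NOT converged)"))
  print(x$summary)
  invisible(x)
}

#' The 18-panel taxonomy of pre/post-quota relationships
#'
#' Trajectory shapes are classified by three component calls: the pre-quota
#' trend (down/flat/up, from \eqn{\beta_3}), the step at quota establishment
#' (down/none/up, from \eqn{\beta_2} for quota levels or \eqn{\beta_1} for
#' actual volumes) and whether the post-quota trend clearly changed (from
#' \eqn{\beta_5} or \eqn{\beta_4}). Panels 1-9 enumerate the pre-trend x
#' step grid with no clear trend change; panels 10-18 repeat the grid with a
#' clear trend change (its direction is reported in the component calls).
#' The mapping is a plain data frame and can be replaced wholesale if a
#' different numbering is preferred.
#'
#' @return Tibble: `panel`, `pre_trend`, `step`, `trend_change`, `label`.
#' @export
panel_grid <- function() {
  base <- tibble::tribble(
    ~panel, ~pre_trend, ~step,
    1L, "flat", "none",
    2L, "up",   "up",
    3L, "flat", "up",
    4L, "up",   "down",
    5L, "up",   "none",
    6L, "down", "none",
    7L, "down", "down",
    8L, "flat", "down",
    9L, "down", "up")
  lab <- function(step, tc) {
    s <- c(none = "no step", up = "step up", down = "step down")[step]
    paste0(s, if (tc == "clear") " + trend change" else "")
  }
  g1 <- base; g1$trend_change <- "none"
  g2 <- base; g2$panel <- g2$panel + 9L; g2$trend_change <- "clear"
  g <- dplyr::bind_rows(g1, g2)
  g$label <- mapply(lab, g$step, g$trend_change)
  g[order(g$panel), ]
}

#' Classify a series into its pre/post-quota panel
#'
#' Component calls use the taxon-level posteriors: the pre-quota trend from
#' \eqn{\beta_3}; the step from \eqn{\beta_2} (`which = "quota_level"`) or
#' \eqn{\beta_1} (`which = "actual_volume"`); the trend change from
#' \eqn{\beta_5} or \eqn{\beta_4}. A direction is "clear" iff at least
#' `threshold` percent of the posterior shares the median's sign (default
#' 97.5), otherwise the component is called flat/none. The triple is mapped
#' to a panel id via [panel_grid()]. Deterministic for a fixed posterior
#' sample and invariant to draw order.
#'
#' @param fit A converged [fit_prepost()] result.
#' @param taxon Taxon whose coefficients to classify.
#' @param which `"quota_level"` or `"actual_volume"`.
#' @param threshold Clear-direction pd threshold (percent).
#' @param grid Panel mapping; default [panel_grid()].
#' @return One-row tibble: `taxon`, `which`, `pre_trend`, `step`,
#'   `trend_change`, `trend_change_direction`, `panel`, `label`.
#' @export
classify_panel <- function(fit, taxon, which = c("quota_level",
                                                 "actual_volume"),
                           threshold = 97.5, grid = panel_grid()) {
  which <- match.arg(which)
  if (!isTRUE(fit$converged))
    stop("fit has not converged; classification blocked")
  if (!taxon %in% names(fit$taxon_draws))
    stop("unknown taxon: ", taxon)
  d <- fit$taxon_draws[[taxon]]
  j <- match(taxon, fit$taxa)
  step_col <- if (which == "quota_level") 2 else 1
  tc_col <- if (which == "quota_level") 5 else 4
  pre <- direction_call(d[, paste0("b[", j, ",3]")], threshold, "flat")
  step <- direction_call(d[, paste0("b[", j, ",", step_col, "]")],
                         threshold, "none")
  tc_dir <- direction_call(d[, paste0("b[", j, ",", tc_col, "]")],
                           threshold, "none")
  tc <- if (tc_dir == "none") "none" else "clear"
  hit <- grid[grid$pre_trend == pre & grid$step == step &
                grid$trend_change == tc, , drop = FALSE]
  tibble::tibble(taxon = taxon, which = which, pre_trend = pre,
                 step = step, trend_change = tc,
                 trend_change_direction = tc_dir,
                 panel = hit$panel[1], label = hit$label[1])
}

#' Classify every taxon in a fit, both panels
#'
#' @param fit A converged [fit_prepost()] result.
#' @inheritParams classify_panel
#' @return Tibble with one row per taxon per target
#'   (quota level and actual volume).
#' @export
classify_all_panels <- function(fit, threshold = 97.5, grid = panel_grid()) {
  dplyr::bind_rows(lapply(fit$taxa, function(tx)
    dplyr::bind_rows(
      classify_panel(fit, tx, "quota_level", threshold, grid),
      classify_panel(fit, tx, "actual_volume", threshold, grid))))
}
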