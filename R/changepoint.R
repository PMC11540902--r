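#' Count quota updates in a year-ordered series
#'
#' Number of times the quota amount differs from the preceding year's value.
#' Translation-invariant in the amounts; a series of length L can have at
#' most L - 1 changes.
#'
#' @param amounts Year-ordered numeric vector of quota amounts (length >= 2).
#' @return Integer count of changes.
#' @export
#' @examples
#' count_changes(c(100, 100, 100))       # 0
#' count_changes(c(100, 200, 200, 150))  # 2
count_changes <- function(amounts) {
  if (length(amounts) < 2) stop("need at least 2 years to count changes")
  sum(diff(amounts) != 0)
}

#' Build quota-update series from cleaned quota records
#'
#' Groups quotas into (taxon, party, scope) time series, splits a series at
#' any gap year (a year with no published quota ends the series — splicing
#' across gaps would conflate "unchanged" with "re-issued"), and counts
#' changes per series. Series containing any zero quota (a ban, in whole or
#' part) are excluded from modelling but reported with
#' `contains_zero_quota = TRUE`; singleton series are dropped.
#'
#' @param quotas Cleaned quota tibble ([clean_quotas()]).
#' @param min_length Minimum series length in years; default 2.
#' @return Tibble: `taxon`, `party`, `scope`, `start_year`, `length`,
#'   `n_changes`, `contains_zero_quota`.
#' @export
build_update_series <- function(quotas, min_length = 2) {
  groups <- split(quotas, paste(quotas$taxon, quotas$party, quotas$scope,
                                sep = "\r"))
  rows <- list()
  for (g in groups) {
    g <- g[order(g$year), , drop = FALSE]
    g <- g[!duplicated(g$year), , drop = FALSE]
    run <- cumsum(c(0L, diff(g$year) > 1))
    for (piece in split(g, run)) {
      if (nrow(piece) < min_length) next
      rows[[length(rows) + 1]] <- tibble::tibble(
        taxon = piece$taxon[1], party = piece$party[1],
        scope = piece$scope[1], start_year = piece$year[1],
        length = nrow(piece),
        n_changes = count_changes(piece$amount),
        contains_zero_quota = any(piece$amount == 0))
    }
  }
  if (!length(rows))
    return(tibble::tibble(taxon = character(), party = character(),
                          scope = character(), start_year = integer(),
                          length = integer(), n_changes = integer(),
                          contains_zero_quota = logical()))
  dplyr::bind_rows(rows)
}

changepoint_jags_model <- "
model {
  for (i in 1:N) {
    y[i] ~ dnorm(mu[i], tau)
    mu[i] <- a + b_pre * min(len[i], omega) + b_post * max(len[i] - omega, 0)
  }
  a ~ dnorm(0, prec_int)
  b_pre ~ dnorm(1, 0.25)
  b_post ~ dnorm(1, 0.25)
  omega ~ dnorm(10, 0.04) T(lo, hi)
  sigma ~ dnorm(0, prec_sd) T(0,)
  tau <- pow(sigma, -2)
}"

#' Fit the nonlinear change-point model of quota-update frequency
#'
#' Regresses the number of quota updates on series length with a continuous
#' two-segment (hinge) mean,
#' \deqn{E[n] = a + s_{pre}\min(L, \omega) + s_{post}\max(L - \omega, 0),}
#' normally distributed residuals, and the stagnation point \eqn{\omega} as
#' a free parameter. The hinge is continuous at \eqn{\omega} for every
#' posterior draw: an adaptively managed portfolio keeps \eqn{s_{post}}
#' close to \eqn{s_{pre}}, whereas \eqn{s_{post}} near zero means long-
#' running quotas stop being updated. Priors: slopes normal(1, 2) — a 1:1
#' update-per-year relationship is the a-priori ideal of adaptive
#' management; \eqn{\omega} normal(10, 5) truncated to the feasible length
#' range; a weak half-normal(0, 2) residual s.d. and normal(0, 5) intercept.
#'
#' @param series Update-series tibble ([build_update_series()]); series
#'   containing zero quotas are dropped here if present.
#' @param chains,warmup,sampling,seed,thin MCMC settings; defaults 4
#'   chains x 500/500, no thinning.
#' @param omega_range Truncation bounds for the change point; default the
#'   feasible series-length range `c(2, 27)`.
#' @param rhat_limit Convergence flag limit; default 1.02.
#' @return A `changepoint_fit` list: `draws`, `summary` (tibble over
#'   intercept, slope_pre, slope_post, omega, sigma; 90% equal-tailed
#'   credible intervals), `length_range`,
#'   `rhat_max`, `converged`, `settings`.
#' @export
fit_changepoint <- function(series, chains = 4, warmup = 500,
                            sampling = 500, seed = 1, thin = 1,
                            omega_range = c(2, 27), rhat_limit = 1.02) {
  series <- series[!series$contains_zero_quota, , drop = FALSE]
  if (nrow(series) < 30)
    warning("fewer than 30 series; change point may be weakly identified",
            call. = FALSE)
  data <- list(N = nrow(series), y = series$n_changes, len = series$length,
               lo = omega_range[1], hi = omega_range[2],
               prec_int = 1 / 25, prec_sd = 1 / 4)
  inits <- lapply(seq_len(chains), function(c)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (seed * 1000L + c) %% 2147483587L))
  jm <- rjags::jags.model(textConnection(changepoint_jags_model),
                          data = data, inits = inits, n.chains = chains,
                          quiet = TRUE)
  stats::update(jm, warmup, progress.bar = "none")
  pars <- c("a", "b_pre", "b_post", "omega", "sigma")
  samp <- rjags::coda.samples(jm, pars, sampling * thin, thin = thin,
                              progress.bar = "none")
  draws <- as.matrix(samp)
  rhat <- max_rhat(samp)
  smry <- dplyr::bind_rows(lapply(pars, function(p)
    summarize_coefficient(draws[, p], interval = "eti")))
  smry <- dplyr::bind_cols(
    tibble::tibble(coef = c("intercept", "slope_pre", "slope_post", "omega",
                            "sigma")), smry)
  structure(list(draws = draws, summary = smry,
                 length_range = range(series$length), rhat_max = rhat,
                 converged = is.finite(rhat) && rhat < rhat_limit,
                 settings = list(chains = chains, warmup = warmup,
                                 sampling = sampling, thin = thin,
                                 seed = seed)),
            class = "changepoint_fit")
}

#' @export
print.changepoint_fit <- function(x, ...) {
  cat("Quota-update change-point fit (hinge mean)\n")
  cat(sprintf("  lengths %d-%d; max Rhat %.3f%s\n", x$length_range[1],
              x$length_range[2], x$rhat_max,
              if (x$converged) "" else " (NOT converged)"))
  print(x$summary)
  invisible(x)
}

#' Posterior expected number of updates at a given series length
#'
#' Evaluates the hinge mean at `length` for every posterior draw and
#' summarizes. Also reports the per-year update rate (median expected
#' changes divided by length, half-up at 2 decimals).
#'
#' @param fit A converged [fit_changepoint()] result.
#' @param length Series length in years (vectorized).
#' @return Tibble: `length`, `median`, `hdi_low`, `hdi_high`, `rate_per_year`.
#' @export
expected_changes <- function(fit, length) {
  if (!isTRUE(fit$converged))
    stop("fit has not converged")
  out <- lapply(length, function(L) {
    if (L < fit$length_range[1] || L > fit$length_range[2])
      warning("length ", L, " outside observed support [",
              fit$length_range[1], ", ", fit$length_range[2], "]",
              call. = FALSE)
    d <- fit$draws
    mu <- d[, "a"] + d[, "b_pre"] * pmin(L, d[, "omega"]) +
      d[, "b_post"] * pmax(L - d[, "omega"], 0)
    s <- summarize_coefficient(mu, interval = "eti")
    tibble::tibble(length = L, median = s$median, hdi_low = s$hdi_low,
                   hdi_high = s$hdi_high,
                   rate_per_year = change_rate(s$median, L))
  })
  dplyr::bind_rows(out)
}

#' Per-year quota update rate
#'
#' @param changes Number of (expected) changes.
#' @param length Series length in years.
#' @param digits Decimal places, half-up; default 2.
#' @return Numeric rate of changes per year.
#' @export
#' @examples
#' change_rate(4, 15)    # 0.27
#' change_rate(4.6, 25)  # 0.18
change_rate <- function(changes, length, digits = 2) {
  round_half_up(changes / length, digits)
}
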