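#' Highest-density interval of a posterior sample
#'
#' The narrowest contiguous interval containing `mass` of the draws,
#' computed by scanning all windows of the sorted sample (the standard
#' empirical HDI estimator for unimodal posteriors).
#'
#' @param draws Numeric vector of posterior draws.
#' @param mass Probability mass; default 0.90.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
hdi <- function(draws, mass = 0.90) {
  draws <- sort(draws[is.finite(draws)])
  n <- length(draws)
  if (n == 0) stop("empty draws")
  k <- max(1L, ceiling(mass * n))
  if (k >= n) return(c(lower = draws[1], upper = draws[n]))
  widths <- draws[(k + 1):n] - draws[1:(n - k)]
  i <- which.min(widths)
  c(lower = draws[i], upper = draws[i + k])
}

#' Probability of direction
#'
#' Share of posterior draws sharing the sign of the posterior median,
#' expressed as a percentage in [50, 100]. A coefficient has a "clear"
#' direction when pd >= 97.5% (equivalent to a 95% credible interval
#' excluding zero for symmetric posteriors).
#'
#' @param draws Numeric vector of posterior draws.
#' @return Percentage in [50, 100].
#' @export
#' @examples
#' prob_direction(c(1, 2, 3))      # 100
prob_direction <- function(draws) {
  draws <- draws[is.finite(draws)]
  if (!length(draws)) stop("empty draws")
  med <- stats::median(draws)
  s <- sign(med)
  if (s == 0) return(50)
  max(50, 100 * mean(sign(draws) == s))
}

#' Summarize a posterior sample
#'
#' Median, 90% interval and probability of direction, the standard
#' reporting triple for coefficient posteriors here. The interval is the
#' highest-density interval by default; `interval = "eti"` gives the
#' equal-tailed (quantile) credible interval instead, the convention used
#' for the change-point model's summaries.
#'
#' @param draws Numeric vector of posterior draws (>= 1000 recommended).
#' @param mass Interval mass; default 0.90.
#' @param interval `"hdi"` (default) or `"eti"`.
#' @return One-row tibble: `median`, `hdi_low`, `hdi_high`, `pd`.
#' @export
summarize_coefficient <- function(draws, mass = 0.90,
                                  interval = c("hdi", "eti")) {
  interval <- match.arg(interval)
  h <- if (interval == "hdi") hdi(draws, mass) else {
    a <- (1 - mass) / 2
    q <- stats::quantile(draws, c(a, 1 - a), names = FALSE)
    c(lower = q[1], upper = q[2])
  }
  tibble::tibble(median = stats::median(draws),
                 hdi_low = unname(h["lower"]),
                 hdi_high = unname(h["upper"]),
                 pd = prob_direction(draws))
}

#' Direction call from a posterior sample
#'
#' `"up"`/`"down"` when the direction is clear (pd >= threshold), otherwise
#' the neutral label.
#'
#' @param draws Posterior draws.
#' @param threshold Clear-direction pd threshold (percent); default 97.5.
#' @param neutral Label when direction is not clear.
#' @return Character scalar.
#' @export
direction_call <- function(draws, threshold = 97.5, neutral = "none") {
  if (prob_direction(draws) >= threshold) {
    if (stats::median(draws) > 0) "up" else "down"
  } else neutral
}

# Max split-chain potential scale reduction factor over monitored parameters
max_rhat <- function(samples) {
  g <- try(coda::gelman.diag(samples, autoburnin = FALSE,
                             multivariate = FALSE), silent = TRUE)
  if (inherits(g, "try-error")) return(NA_real_)
  max(g$psrf[, 1], na.rm = TRUE)
}
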