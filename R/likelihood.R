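#' Censored lognormal log-likelihood components
#'
#' The model takes log10 concentrations \eqn{y = \log_{10}(x)} to be
#' normally distributed with mean `mu` and standard deviation `sigma` (both
#' in log10 CFU/g).  A quantified sample contributes the normal log-density
#' at its value; an ND sample contributes the log of the probability mass
#' below the LOQ; a semi-quantitative sample contributes the log of the
#' mass inside its class.  All computation is in log space: with hundreds
#' or thousands of censored samples the raw product of probabilities
#' underflows double precision.
#'
#' @param y Log10 concentration(s).
#' @param mu,sigma Parameters of the log10-normal (sigma > 0).
#' @return `log_density()`: the normal log-density
#'   \eqn{-\log(\sqrt{2\pi}\sigma) - (y-\mu)^2/(2\sigma^2)}.
#' @examples
#' log_density(2, mu = 2, sigma = 1)           # -log(sqrt(2*pi))
#' exp(log_prob_below(2, mu = 2, sigma = 1))   # 0.5
#' exp(log_prob_interval(1, 3, mu = 2, sigma = 1))  # 0.6827
#' @export
log_density <- function(y, mu, sigma) {
  check_params(mu, sigma)
  -log(sqrt(2 * pi) * sigma) - (y - mu)^2 / (2 * sigma^2)
}

#' @rdname log_density
#' @param threshold Log10 concentration below which the observation is
#'   known to lie (for ND data, `log10(loq)`).
#' @return `log_prob_below()`: \eqn{\log \Phi((threshold-\mu)/\sigma)},
#'   computed with the numerically stable log-CDF so that deep-tail
#'   arguments (z down to -30 and far beyond) do not underflow to
#'   `-Inf`.
#' @export
log_prob_below <- function(threshold, mu, sigma) {
  check_params(mu, sigma)
  stats::pnorm(threshold, mean = mu, sd = sigma, log.p = TRUE)
}

#' @rdname log_density
#' @param lower,upper Log10 class bounds, `lower < upper`.
#' @return `log_prob_interval()`:
#'   \eqn{\log[\Phi((upper-\mu)/\sigma) - \Phi((lower-\mu)/\sigma)]}.  The
#'   difference is evaluated on the nearer tail (upper-tail form when the
#'   class lies above `mu`), which keeps it accurate for classes far out in
#'   either tail where the two CDF values would otherwise cancel.
#' @export
log_prob_interval <- function(lower, upper, mu, sigma) {
  check_params(mu, sigma)
  if (any(lower >= upper)) stop("'lower' must be < 'upper'", call. = FALSE)
  zl <- (lower - mu) / sigma
  zu <- (upper - mu) / sigma
  # work on the tail where both CDF values are small, so the difference
  # keeps relative precision
  p <- ifelse(zl + zu > 0,
              stats::pnorm(zl, lower.tail = FALSE) -
                stats::pnorm(zu, lower.tail = FALSE),
              stats::pnorm(zu) - stats::pnorm(zl))
  out <- suppressWarnings(log(p))
  # floating cancellation can still return 0 for extreme classes; fall
  # back to the dominant tail mass, a tight lower bound on the class mass
  bad <- !is.finite(out)
  if (any(bad)) {
    tail_lp <- ifelse(zl + zu > 0,
                      stats::pnorm(zl, lower.tail = FALSE, log.p = TRUE),
                      stats::pnorm(zu, log.p = TRUE))
    out[bad] <- pmax(tail_lp[bad] + log(.Machine$double.eps), -745)
  }
  out
}

#' Total censored log-likelihood of an enumeration dataset
#'
#' Sums, over all observations, the weight times the appropriate
#' log-likelihood term: [log_density()] for exact values,
#' [log_prob_below()] at the ND bound for left-censored values, and
#' [log_prob_interval()] for semi-quantitative classes.  With only exact
#' and left-censored data this is the log of the classical censored-data
#' likelihood (product of densities times the below-LOQ probability raised
#' to the number of ND samples).
#'
#' @param x An `"enum_data"` object.
#' @param mu,sigma Parameters of the log10-normal (sigma > 0).
#' @return The log-likelihood, a finite scalar for finite parameters.
#' @examples
#' d <- enum_quantitative(c(20, NA, 300), loq = 10)
#' total_loglik(d, mu = 2, sigma = 1)
#' @export
total_loglik <- function(x, mu, sigma) {
  stopifnot(inherits(x, "enum_data"))
  check_params(mu, sigma)
  o <- x$observations
  ll <- 0
  ex <- o$kind == "exact"
  if (any(ex))
    ll <- ll + sum(o$weight[ex] * log_density(o$value[ex], mu, sigma))
  lc <- o$kind == "left_censored"
  if (any(lc))
    ll <- ll + sum(o$weight[lc] * log_prob_below(o$upper[lc], mu, sigma))
  iv <- o$kind == "interval"
  if (any(iv))
    ll <- ll + sum(o$weight[iv] *
                     log_prob_interval(o$lower[iv], o$upper[iv], mu, sigma))
  ll
}

check_params <- function(mu, sigma) {
  if (!is.numeric(mu) || !all(is.finite(mu)))
    stop("'mu' must be finite", call. = FALSE)
  if (!is.numeric(sigma) || !all(is.finite(sigma)) || any(sigma <= 0))
    stop("'sigma' must be strictly positive and finite", call. = FALSE)
  invisible(TRUE)
}
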