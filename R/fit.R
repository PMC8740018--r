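#' Fit a log10-normal concentration distribution by maximum likelihood
#'
#' Maximises the censored-data log-likelihood ([total_loglik()]) over
#' `(mu, log sigma)`, so `sigma > 0` is structural.  A derivative-free
#' Nelder-Mead search from a substitution-based start point is refined by
#' BFGS.  The result carries Wald standard errors and confidence intervals
#' from the observed information (numerical Hessian), the 5th and 95th
#' percentiles of the fitted distribution, and convergence diagnostics.
#'
#' @section Interval-data conventions:
#' Two treatments of semi-quantitative class data are available.
#'
#' * `"interval"` (default): each class contributes its exact probability
#'   mass \eqn{\Phi(u) - \Phi(l)} to the likelihood.  This is the
#'   statistically efficient treatment of grouped data.
#' * `"classic"`: each detected class is collapsed to a point observation
#'   at the log10 of its linear-scale midpoint (e.g. 55 CFU/g for the
#'   10--10^2 class), and the ND class of a semi-quantitative table is
#'   censored at `log10(loq - 1)`, reading the classes as discrete
#'   plate-count ranges (ND = 0..loq-1 CFU/g).  This reproduces the
#'   historical spreadsheet treatment of semi-quantitative survey tables;
#'   see the package vignette for a comparison.
#'
#' The conventions coincide for purely quantitative data.
#'
#' @param x An `"enum_data"` object with at least one non-censored
#'   observation and total weight >= 2.
#' @param convention `"interval"` or `"classic"`; see Details.
#' @param level Confidence level for the Wald intervals (default 0.95).
#' @param tol Relative convergence tolerance on the log-likelihood
#'   (default 1e-10).
#' @param max_iter Maximum optimiser iterations (default 2000).
#'
#' @return An object of class `"enum_fit"`: a list with components
#'   `mu`, `sigma`, `se_mu`, `se_sigma`, `ci_mu`, `ci_sigma`, `loglik`,
#'   `converged`, `iterations`, `n_detected`, `m_censored`, `p05`, `p95`,
#'   `loq_log10`, `level`, `convention`, `method` and the fitted `data`.
#' @seealso [summarize_uncensored()] for the censoring-free closed form,
#'   [density_table()] and [enum_report()] for reporting.
#' @examples
#' d <- enum_intervals(lower = 10^(1:5), upper = 10^(2:6),
#'                     count = c(258, 368, 234, 44, 2), nd = 214, loq = 10)
#' fit <- fit_enum(d, convention = "classic")
#' coef(fit)
#' @export
fit_enum <- function(x, convention = c("interval", "classic"),
                     level = 0.95, tol = 1e-10, max_iter = 2000) {
  stopifnot(inherits(x, "enum_data"))
  convention <- match.arg(convention)
  if (n_detected(x) == 0)
    stop(paste0("dataset is fully censored (100% ND): a lognormal cannot ",
                "be identified from below-LOQ observations alone"),
         call. = FALSE)
  if (n_detected(x) + m_censored(x) < 2)
    stop("at least 2 observations are required", call. = FALSE)
  xf <- apply_convention(x, convention)
  start <- init_params(xf)
  nll <- function(th) -total_loglik(xf, th[1], exp(th[2]))
  th0 <- c(start[["mu"]], log(start[["sigma"]]))
  o1 <- stats::optim(th0, nll, method = "Nelder-Mead",
                     control = list(reltol = tol, maxit = max_iter))
  o2 <- tryCatch(
    stats::optim(o1$par, nll, method = "BFGS",
                 control = list(reltol = tol, maxit = max_iter)),
    error = function(e) o1)
  best <- if (o2$value <= o1$value) o2 else o1
  converged <- (o1$convergence == 0L || o2$convergence == 0L)
  if (!converged)
    warning("optimiser did not converge within ", max_iter, " iterations")
  mu <- best$par[1]
  sigma <- exp(best$par[2])
  wald <- wald_confidence(xf, mu, sigma, level = level)
  z <- stats::qnorm(0.5 + level / 2)
  res <- structure(list(
    mu = mu, sigma = sigma,
    se_mu = wald$se_mu, se_sigma = wald$se_sigma,
    ci_mu = wald$ci_mu, ci_sigma = wald$ci_sigma,
    loglik = -best$value,
    loglik_start = -nll(th0),
    converged = converged,
    iterations = sum(o1$counts[1], o2$counts[1], na.rm = TRUE),
    n_detected = n_detected(x), m_censored = m_censored(x),
    p05 = mu - stats::qnorm(0.95) * sigma,
    p95 = mu + stats::qnorm(0.95) * sigma,
    loq_log10 = log10(x$loq),
    level = level, convention = convention, method = "mle",
    data = x), class = "enum_fit")
  res
}

# Transform a dataset according to the chosen interval-data convention.
# "classic" collapses semi-quantitative classes to their linear-midpoint
# log10 values and censors the ND class of such tables at log10(loq - 1),
# the upper bound of the ND count range in a discrete class reading.
apply_convention <- function(x, convention) {
  if (convention != "classic") return(x)
  o <- x$observations
  iv <- o$kind == "interval"
  if (!any(iv)) return(x)
  mid <- (o$lin_lower[iv] + o$lin_upper[iv]) / 2
  o$value[iv] <- log10(mid)
  o$lin_value[iv] <- mid
  o$kind[iv] <- "exact"
  o$lower[iv] <- NA_real_; o$upper[iv] <- NA_real_
  o$lin_lower[iv] <- NA_real_; o$lin_upper[iv] <- NA_real_
  lc <- o$kind == "left_censored"
  if (any(lc) && x$loq > 1) {
    o$upper[lc] <- log10(x$loq - 1)
    o$lin_upper[lc] <- x$loq - 1
  }
  y <- x
  y$observations <- o
  # mode is part of the source data's identity; keep it
  y
}

#' Substitution-based starting point for the optimiser
#'
#' Replaces each left-censored observation by `log10(loq/2)` and each
#' interval observation by its log-scale midpoint, then returns the
#' weighted mean and the weighted n-denominator SD of the substituted
#' values (floored at 0.05 to avoid a degenerate start).
#'
#' @param x An `"enum_data"` object with at least one non-censored
#'   observation.
#' @return Named numeric vector `c(mu = ..., sigma = ...)`.
#' @export
init_params <- function(x) {
  stopifnot(inherits(x, "enum_data"))
  if (n_detected(x) == 0)
    stop("cannot initialise from a fully censored dataset", call. = FALSE)
  o <- x$observations
  v <- ifelse(o$kind == "exact", o$value,
              ifelse(o$kind == "interval", (o$lower + o$upper) / 2,
                     o$upper + log10(0.5)))  # log10(loq/2)
  w <- o$weight
  mu0 <- sum(w * v) / sum(w)
  s0 <- sqrt(sum(w * (v - mu0)^2) / sum(w))
  c(mu = mu0, sigma = max(s0, 0.05))
}

#' Wald standard errors and confidence intervals at the MLE
#'
#' Differentiates [total_loglik()] twice by central finite differences in
#' `(mu, sigma)` (step `1e-5 * max(1, |theta|)`), inverts the negative
#' Hessian (the observed information) and forms
#' `estimate +/- z * SE` intervals.  If the Hessian is not positive
#' definite the standard errors are reported as `NA` with a warning.
#'
#' @param x An `"enum_data"` object.
#' @param mu,sigma The maximum-likelihood estimates for `x`.
#' @param level Confidence level (default 0.95).
#' @return A list with `se_mu`, `se_sigma`, `ci_mu`, `ci_sigma`.
#' @export
wald_confidence <- function(x, mu, sigma, level = 0.95) {
  H <- numeric_hessian(function(th) total_loglik(x, th[1], th[2]),
                       c(mu, sigma))
  z <- stats::qnorm(0.5 + level / 2)
  info <- -H
  ok <- all(is.finite(info)) &&
    info[1, 1] > 0 && det(info) > 0  # positive definite 2x2
  if (!ok) {
    warning("observed information is not positive definite; ",
            "standard errors unavailable")
    se <- c(NA_real_, NA_real_)
  } else {
    V <- solve(info)
    se <- sqrt(diag(V))
  }
  list(se_mu = se[1], se_sigma = se[2],
       ci_mu = c(mu - z * se[1], mu + z * se[1]),
       ci_sigma = c(sigma - z * se[2], sigma + z * se[2]))
}

numeric_hessian <- function(f, theta, rel_step = 1e-5) {
  k <- length(theta)
  h <- rel_step * pmax(1, abs(theta))
  H <- matrix(NA_real_, k, k)
  f0 <- f(theta)
  for (i in seq_len(k)) {
    ei <- replace(numeric(k), i, h[i])
    H[i, i] <- (f(theta + ei) - 2 * f0 + f(theta - ei)) / h[i]^2
    if (i < k) for (j in seq(i + 1, k)) {
      ej <- replace(numeric(k), j, h[j])
      H[i, j] <- H[j, i] <-
        (f(theta + ei + ej) - f(theta + ei - ej) -
           f(theta - ei + ej) + f(theta - ei - ej)) / (4 * h[i] * h[j])
    }
  }
  H
}

#' Closed-form summary for censoring-free data
#'
#' With no ND observations the maximum-likelihood estimates for exact data
#' are the sample mean and the n-denominator standard deviation of the
#' log10 values, so no iterative fit is needed; interval-only (QN_2) data
#' still route through [fit_enum()].  The n-denominator SD (not n-1) is
#' used so that all paths agree exactly in the censoring-free limit.
#'
#' @param x An `"enum_data"` object without censored observations.
#' @param level Confidence level for the Wald intervals.
#' @return An `"enum_fit"` object (with `method = "closed_form"` for exact
#'   data).
#' @examples
#' summarize_uncensored(enum_quantitative(c(10, 100, 1000), loq = 10))
#' @export
summarize_uncensored <- function(x, level = 0.95) {
  stopifnot(inherits(x, "enum_data"))
  if (m_censored(x) > 0)
    stop("dataset contains censored (ND) observations: use fit_enum()",
         call. = FALSE)
  o <- x$observations
  if (any(o$kind == "interval")) return(fit_enum(x, level = level))
  v <- rep(o$value, o$weight)
  n <- length(v)
  mu <- mean(v)
  sigma <- sqrt(sum((v - mu)^2) / n)
  if (sigma == 0) {
    warning("all observations identical: sigma is degenerate (0)")
    wald <- list(se_mu = NA_real_, se_sigma = NA_real_,
                 ci_mu = c(NA_real_, NA_real_),
                 ci_sigma = c(NA_real_, NA_real_))
    ll <- NA_real_
  } else {
    wald <- wald_confidence(x, mu, sigma, level = level)
    ll <- total_loglik(x, mu, sigma)
  }
  structure(list(
    mu = mu, sigma = sigma,
    se_mu = wald$se_mu, se_sigma = wald$se_sigma,
    ci_mu = wald$ci_mu, ci_sigma = wald$ci_sigma,
    loglik = ll, loglik_start = ll,
    converged = TRUE, iterations = 0L,
    n_detected = n_detected(x), m_censored = 0L,
    p05 = mu - stats::qnorm(0.95) * sigma,
    p95 = mu + stats::qnorm(0.95) * sigma,
    loq_log10 = log10(x$loq),
    level = level, convention = "interval", method = "closed_form",
    data = x), class = "enum_fit")
}
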