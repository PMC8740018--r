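#' @export
print.enum_fit <- function(x, ...) {
  cat("Censored log10-normal fit (", x$method,
      if (x$method == "mle") paste0(", ", x$convention, " convention"),
      ")\n", sep = "")
  cat(sprintf("  n detected: %d   ND (censored): %d (%.1f%%)   LOQ: 10^%.4g CFU/g\n",
              x$n_detected, x$m_censored,
              100 * x$m_censored / (x$n_detected + x$m_censored),
              x$loq_log10))
  cat(sprintf("  mean  (log10 CFU/g): %.2f  [%s %.2f, %.2f]\n",
              x$mu, paste0(100 * x$level, "% CI"),
              x$ci_mu[1], x$ci_mu[2]))
  cat(sprintf("  SD    (log10 CFU/g): %.2f  [%s %.2f, %.2f]\n",
              x$sigma, paste0(100 * x$level, "% CI"),
              x$ci_sigma[1], x$ci_sigma[2]))
  cat(sprintf("  5th / 95th percentile: %.2f / %.2f log10 CFU/g\n",
              x$p05, x$p95))
  if (is.finite(x$loglik))
    cat(sprintf("  log-likelihood: %.4f   converged: %s\n",
                x$loglik, x$converged))
  invisible(x)
}

#' @export
summary.enum_fit <- function(object, ...) {
  est <- data.frame(
    estimate = c(object$mu, object$sigma),
    se = c(object$se_mu, object$se_sigma),
    ci_lower = c(object$ci_mu[1], object$ci_sigma[1]),
    ci_upper = c(object$ci_mu[2], object$ci_sigma[2]),
    row.names = c("mu", "sigma"))
  out <- list(coefficients = est, loglik = object$loglik,
              converged = object$converged,
              iterations = object$iterations,
              n_detected = object$n_detected,
              m_censored = object$m_censored,
              censored_pct = 100 * object$m_censored /
                (object$n_detected + object$m_censored),
              p05 = object$p05, p95 = object$p95,
              level = object$level, method = object$method,
              convention = object$convention)
  class(out) <- "summary.enum_fit"
  out
}

#' @export
print.summary.enum_fit <- function(x, digits = 4, ...) {
  cat("Censored log10-normal fit summary\n\n")
  print(round(x$coefficients, digits))
  cat(sprintf("\nn detected: %d   ND: %d (%.1f%%)\n",
              x$n_detected, x$m_censored, x$censored_pct))
  cat(sprintf("percentiles (5th, 95th): %.*f, %.*f log10 CFU/g\n",
              digits, x$p05, digits, x$p95))
  if (is.finite(x$loglik))
    cat(sprintf("log-likelihood %.*f, converged %s (%d evaluations)\n",
                digits, x$loglik, x$converged, x$iterations))
  invisible(x)
}

#' @export
coef.enum_fit <- function(object, ...) {
  c(mu = object$mu, sigma = object$sigma)
}

#' @export
logLik.enum_fit <- function(object, ...) {
  structure(object$loglik, df = 2L,
            nobs = object$n_detected + object$m_censored,
            class = "logLik")
}

#' @export
vcov.enum_fit <- function(object, ...) {
  # reconstruct from the stored SEs is lossy; recompute the information
  xf <- apply_convention(object$data, object$convention)
  H <- numeric_hessian(function(th) total_loglik(xf, th[1], th[2]),
                       c(object$mu, object$sigma))
  V <- solve(-H)
  dimnames(V) <- list(c("mu", "sigma"), c("mu", "sigma"))
  V
}

#' @export
confint.enum_fit <- function(object, parm = c("mu", "sigma"),
                             level = NULL, ...) {
  parm <- match.arg(parm, several.ok = TRUE)
  if (is.null(level) || isTRUE(all.equal(level, object$level))) {
    ci <- rbind(mu = object$ci_mu, sigma = object$ci_sigma)
  } else {
    xf <- apply_convention(object$data, object$convention)
    w <- wald_confidence(xf, object$mu, object$sigma, level = level)
    ci <- rbind(mu = w$ci_mu, sigma = w$ci_sigma)
  }
  lv <- if (is.null(level)) object$level else level
  colnames(ci) <- sprintf("%.1f %%", 100 * c(0.5 - lv / 2, 0.5 + lv / 2))
  ci[parm, , drop = FALSE]
}

#' Predictions from a fitted concentration distribution
#'
#' @param object An `"enum_fit"`.
#' @param at Log10 concentrations (for `type` `"density"` and `"cdf"`) or
#'   probabilities (for `type = "quantile"`).
#' @param type What to return: the fitted density, the cumulative
#'   probability, or the quantile, all on the log10 CFU/g scale.
#' @param ... Unused.
#' @return Numeric vector of the same length as `at`.
#' @examples
#' d <- enum_quantitative(c(15, NA, 40, 200, NA, 1200), loq = 10)
#' f <- fit_enum(d)
#' predict(f, at = c(0.05, 0.5, 0.95), type = "quantile")
#' @export
predict.enum_fit <- function(object, at,
                             type = c("density", "cdf", "quantile"), ...) {
  type <- match.arg(type)
  switch(type,
         density = exp(log_density(at, object$mu, object$sigma)),
         cdf = stats::pnorm(at, object$mu, object$sigma),
         quantile = stats::qnorm(at, object$mu, object$sigma))
}

#' Simulate new enumeration datasets from a fitted distribution
#'
#' Draws datasets from the fitted log10-normal with the LOQ (and, for
#' interval data, the class bounds) of the original data.
#'
#' @param object An `"enum_fit"`.
#' @param nsim Number of datasets.
#' @param seed Integer seed (optional).
#' @param n Samples per dataset; defaults to the size of the fitted data.
#' @param ... Unused.
#' @return A list of `"enum_data"` objects (length `nsim`).
#' @export
simulate.enum_fit <- function(object, nsim = 1, seed = NULL, n = NULL, ...) {
  n <- if (is.null(n)) object$n_detected + object$m_censored else n
  x <- object$data
  iv <- x$observations$kind == "interval"
  mode <- if (any(iv)) "interval" else "quantitative"
  edges <- if (any(iv))
    sort(unique(c(x$observations$lower[iv], x$observations$upper[iv])))
  base <- if (is.null(seed)) sample.int(1e6, 1) else seed
  lapply(seq_len(nsim), function(i)
    simulate_enum(mu = object$mu, sigma = object$sigma, n = n,
                  loq = x$loq, mode = mode, bin_edges = edges,
                  seed = base + i - 1L))
}

#' Plot a fitted concentration distribution
#'
#' Draws the fitted log10-normal density with vertical markers at the
#' mean, the LOQ and the 5th and 95th percentiles, the standard output
#' display for a censored enumeration fit.
#'
#' @param x An `"enum_fit"`.
#' @param grid_points Number of grid points (default 201).
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the [density_table()] used for drawing.
#' @export
plot.enum_fit <- function(x, grid_points = 201, ...) {
  tab <- density_table(x, grid_points = grid_points)
  graphics::plot(tab$log10_conc, tab$density, type = "l",
                 xlab = "concentration (log10 CFU/g)",
                 ylab = "fitted probability density", ...)
  mk <- c(mean = x$mu, loq = x$loq_log10, p05 = x$p05, p95 = x$p95)
  cols <- c("black", "red", "grey40", "grey40")
  lty <- c(2, 1, 3, 3)
  graphics::abline(v = mk, col = cols, lty = lty)
  graphics::legend("topright",
                   legend = c(sprintf("mean = %.2f", x$mu),
                              sprintf("LOQ = %.2f", x$loq_log10),
                              sprintf("5th pct = %.2f", x$p05),
                              sprintf("95th pct = %.2f", x$p95)),
                   col = cols, lty = lty, bty = "n", cex = 0.85)
  invisible(tab)
}
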