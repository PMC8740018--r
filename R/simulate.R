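#' Simulate an enumeration dataset with known parameters
#'
#' Draws `n` log10 concentrations from Normal(`mu`, `sigma`).  Values below
#' `log10(loq)` become ND (left-censored) observations.  Detected values
#' are kept exactly in `"quantitative"` mode, or grouped into classes in
#' `"interval"` mode; simulated values above the last class edge are
#' clamped into the top class with a warning, mirroring the finite class
#' range of semi-quantitative report tables.
#'
#' @param mu,sigma True parameters on the log10 CFU/g scale (`sigma > 0`).
#' @param n Number of samples (>= 1).
#' @param loq Limit of quantification in CFU/g.
#' @param mode `"quantitative"` or `"interval"`.
#' @param bin_edges Ascending log10 class edges for interval mode, starting
#'   at `log10(loq)`; default decade classes spanning `loq` to `loq x 10^5`.
#' @param seed Integer seed; when given, the draw is reproducible and the
#'   caller's RNG state is left untouched.
#' @param label Dataset label.
#' @return An `"enum_data"` object.  An all-ND draw is returned as data
#'   (it can arise under heavy censoring); [fit_enum()] will refuse it.
#' @examples
#' d <- simulate_enum(mu = 2.3, sigma = 1.3, n = 500, loq = 10, seed = 1)
#' censored_fraction(d)
#' @export
simulate_enum <- function(mu, sigma, n, loq,
                          mode = c("quantitative", "interval"),
                          bin_edges = NULL, seed = NULL, label = "") {
  mode <- match.arg(mode)
  check_params(mu, sigma)
  stopifnot(n >= 1, loq > 0)
  y <- with_seed(seed, stats::rnorm(n, mu, sigma))
  b0 <- log10(loq)
  nd <- sum(y < b0)
  det <- y[y >= b0]
  if (mode == "quantitative") {
    obs <- NULL
    if (length(det))
      obs <- data.frame(kind = "exact", value = det,
                        lower = NA_real_, upper = NA_real_,
                        lin_value = 10^det, lin_lower = NA_real_,
                        lin_upper = NA_real_, weight = 1L)
    if (nd > 0)
      obs <- rbind(obs,
                   data.frame(kind = "left_censored", value = NA_real_,
                              lower = NA_real_, upper = b0,
                              lin_value = NA_real_, lin_lower = NA_real_,
                              lin_upper = loq, weight = as.integer(nd)))
    return(new_enum_data(obs, loq, label, allow_all_censored = TRUE))
  }
  if (is.null(bin_edges)) bin_edges <- b0 + 0:5
  if (length(bin_edges) < 2 || is.unsorted(bin_edges, strictly = TRUE))
    stop("'bin_edges' must be >= 2 strictly increasing log10 bounds",
         call. = FALSE)
  if (abs(bin_edges[1] - b0) > 1e-9)
    stop("'bin_edges' must start at log10(loq)", call. = FALSE)
  over <- sum(det >= bin_edges[length(bin_edges)])
  if (over > 0) {
    warning(over, " simulated value(s) above the last class edge were ",
            "clamped into the top class")
    det <- pmin(det, bin_edges[length(bin_edges)] - 1e-9)
  }
  cls <- cut(det, breaks = bin_edges, right = FALSE,
             include.lowest = FALSE)
  counts <- as.integer(table(cls))
  k <- length(bin_edges) - 1L
  keep <- counts > 0
  obs <- NULL
  if (any(keep)) {
    lo <- bin_edges[seq_len(k)][keep]
    hi <- bin_edges[-1L][keep]
    obs <- data.frame(kind = "interval", value = NA_real_,
                      lower = lo, upper = hi,
                      lin_value = NA_real_, lin_lower = 10^lo,
                      lin_upper = 10^hi, weight = counts[keep])
  }
  if (nd > 0)
    obs <- rbind(obs,
                 data.frame(kind = "left_censored", value = NA_real_,
                            lower = NA_real_, upper = b0,
                            lin_value = NA_real_, lin_lower = NA_real_,
                            lin_upper = loq, weight = as.integer(nd)))
  new_enum_data(obs, loq, label, allow_all_censored = TRUE)
}

# run code under a temporary seed without disturbing the session RNG
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Parameter-recovery study
#'
#' Repeatedly simulates datasets with known `(mu, sigma)` and refits them,
#' to quantify the bias and root-mean-square error of the censored MLE
#' under a given censoring regime.  Replicate `r` uses seed `seed + r`, so
#' studies are exactly repeatable.
#'
#' @inheritParams simulate_enum
#' @param replicates Number of replicates (>= 1).
#' @param convention Passed to [fit_enum()].
#' @param seed Base seed (default 1).
#' @return A data.frame with columns `replicate`, `mu_hat`, `sigma_hat`,
#'   `converged` (fit failures yield `NA` rows, not errors), of class
#'   `"recovery_study"`, with the truth and bias/RMSE summaries attached
#'   as attributes (`attr(x, "summary")`).
#' @examples
#' rs <- recovery_study(mu = 2, sigma = 1, n = 300, loq = 10,
#'                      replicates = 5, seed = 42)
#' attr(rs, "summary")
#' @export
recovery_study <- function(mu, sigma, n, loq, replicates,
                           mode = c("quantitative", "interval"),
                           bin_edges = NULL,
                           convention = c("interval", "classic"),
                           seed = 1) {
  mode <- match.arg(mode)
  convention <- match.arg(convention)
  stopifnot(replicates >= 1)
  rows <- lapply(seq_len(replicates), function(r) {
    fit <- tryCatch({
      d <- simulate_enum(mu, sigma, n, loq, mode = mode,
                         bin_edges = bin_edges, seed = seed + r)
      suppressWarnings(fit_enum(d, convention = convention))
    }, error = function(e) NULL)
    if (is.null(fit))
      data.frame(replicate = r, mu_hat = NA_real_, sigma_hat = NA_real_,
                 converged = FALSE)
    else
      data.frame(replicate = r, mu_hat = fit$mu, sigma_hat = fit$sigma,
                 converged = fit$converged)
  })
  out <- do.call(rbind, rows)
  ok <- stats::complete.cases(out)
  attr(out, "truth") <- c(mu = mu, sigma = sigma)
  attr(out, "summary") <- c(
    bias_mu = mean(out$mu_hat[ok]) - mu,
    bias_sigma = mean(out$sigma_hat[ok]) - sigma,
    rmse_mu = sqrt(mean((out$mu_hat[ok] - mu)^2)),
    rmse_sigma = sqrt(mean((out$sigma_hat[ok] - sigma)^2)),
    n_failed = sum(!ok))
  class(out) <- c("recovery_study", "data.frame")
  out
}

#' Naive substitution summaries for censored data
#'
#' Computes the mean and n-denominator SD of the log10 values after
#' handling ND observations by a naive substitution rule, the common
#' practice that censored-data MLE replaces:
#' `"ignore_nd"` drops ND samples; `"loq"` substitutes the LOQ;
#' `"half_loq"` substitutes LOQ/2; `"zero_excluded"` substitutes zero and
#' then excludes the undefined logs (arithmetically identical to
#' `"ignore_nd"`).  Interval observations enter at their log-scale class
#' midpoint.
#'
#' @param x An `"enum_data"` object.
#' @param rule Substitution rule, see Details.
#' @return Named numeric vector `c(mu = ..., sigma = ...)`.
#' @examples
#' d <- simulate_enum(2, 1, 200, loq = 10, seed = 3)
#' substitution_summary(d, "half_loq")
#' coef(fit_enum(d))
#' @export
substitution_summary <- function(x, rule = c("ignore_nd", "loq",
                                             "half_loq", "zero_excluded")) {
  stopifnot(inherits(x, "enum_data"))
  rule <- match.arg(rule)
  o <- x$observations
  v <- ifelse(o$kind == "exact", o$value, (o$lower + o$upper) / 2)
  lc <- o$kind == "left_censored"
  v[lc] <- switch(rule,
                  ignore_nd = NA_real_,
                  zero_excluded = NA_real_,
                  loq = log10(x$loq),
                  half_loq = log10(x$loq / 2))
  keep <- !is.na(v)
  vals <- rep(v[keep], o$weight[keep])
  if (!length(vals))
    stop("no usable observations under rule '", rule, "'", call. = FALSE)
  mu <- mean(vals)
  c(mu = mu, sigma = sqrt(mean((vals - mu)^2)))
}
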