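#' Fitted-density curve table for plotting
#'
#' Tabulates the fitted log10-normal density on an even grid spanning
#' `mu +/- 4 sigma`, with extra rows inserted (and flagged in the `marker`
#' column) at the mean, the LOQ and the 5th and 95th percentiles — the
#' quantities a concentration-distribution plot displays.
#'
#' @param fit A converged `"enum_fit"`.
#' @param grid_points Number of evenly spaced grid points (default 201).
#' @return A data.frame with columns `log10_conc`, `density`, `marker`
#'   (`""`, `"mean"`, `"loq"`, `"p05"`, `"p95"`).
#' @examples
#' f <- fit_enum(enum_quantitative(c(15, NA, 40, 200, 800), loq = 10))
#' head(density_table(f))
#' @export
density_table <- function(fit, grid_points = 201) {
  stopifnot(inherits(fit, "enum_fit"))
  if (!isTRUE(fit$converged))
    stop("density table requires a converged fit", call. = FALSE)
  if (grid_points < 2) stop("'grid_points' must be >= 2", call. = FALSE)
  g <- seq(fit$mu - 4 * fit$sigma, fit$mu + 4 * fit$sigma,
           length.out = grid_points)
  tab <- data.frame(log10_conc = g, marker = "")
  mk <- data.frame(log10_conc = c(fit$mu, fit$loq_log10, fit$p05, fit$p95),
                   marker = c("mean", "loq", "p05", "p95"))
  tab <- rbind(tab, mk)
  tab <- tab[order(tab$log10_conc), ]
  tab$density <- exp(log_density(tab$log10_conc, fit$mu, fit$sigma))
  rownames(tab) <- NULL
  tab[, c("log10_conc", "density", "marker")]
}

#' Build a structured report for a fitted dataset
#'
#' Collects the dataset summary (n, ND count, censored percentage, LOQ),
#' the estimates with standard errors, confidence intervals and
#' percentiles, convergence diagnostics, and provenance (input path and
#' MD5 hash when the data came from a file, sub-tool mode, package
#' version, timestamp).  `format = "text"` renders the same numbers
#' rounded to the reporting precision (2 decimals for log-scale estimates,
#' 1 for percentages).
#'
#' @param fit An `"enum_fit"`.
#' @param input_path Optional path of the source file, recorded (with its
#'   MD5 hash) as provenance.
#' @param format `"list"` for the machine-readable structure, `"text"` for
#'   the human-readable rendering (a character vector of lines), `"json"`
#'   for a JSON string of the machine structure.
#' @return See `format`.
#' @examples
#' f <- fit_enum(enum_quantitative(c(15, NA, 40, 200, 800), loq = 10))
#' cat(enum_report(f, format = "text"), sep = "\n")
#' @export
enum_report <- function(fit, input_path = NULL,
                        format = c("list", "text", "json")) {
  stopifnot(inherits(fit, "enum_fit"))
  format <- match.arg(format)
  total <- fit$n_detected + fit$m_censored
  rep <- list(
    schema_version = "1.0",
    tool = list(package = "cfufit",
                version = as.character(utils::packageVersion("cfufit")),
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    input = list(
      path = if (is.null(input_path)) NA_character_ else input_path,
      md5 = if (is.null(input_path)) NA_character_
            else unname(tools::md5sum(input_path)),
      mode = fit$data$mode,
      label = fit$data$label),
    data = list(n_total = total, n_detected = fit$n_detected,
                m_censored = fit$m_censored,
                censored_pct = 100 * fit$m_censored / total,
                loq_cfu = fit$data$loq,
                loq_log10 = fit$loq_log10),
    fit = list(method = fit$method, convention = fit$convention,
               mean_log10 = fit$mu, sd_log10 = fit$sigma,
               se_mean = fit$se_mu, se_sd = fit$se_sigma,
               ci_level = fit$level,
               ci_mean = fit$ci_mu, ci_sd = fit$ci_sigma,
               p05 = fit$p05, p95 = fit$p95,
               loglik = fit$loglik, converged = fit$converged,
               iterations = fit$iterations))
  if (format == "list") return(rep)
  if (format == "json")
    return(jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA,
                            na = "null", pretty = TRUE))
  qn_note <- if (fit$m_censored == 0)
    "no censored data; MLE not required (plain summary applies)"
  else sprintf("%s sub-tool path (censored data present; MLE used)",
               fit$data$mode)
  c(sprintf("Microbial concentration estimate%s",
            if (nzchar(fit$data$label)) paste0(" - ", fit$data$label) else ""),
    sprintf("  samples: %d total, %d detected, %d ND (%.1f%% censored)",
            total, fit$n_detected, fit$m_censored,
            rep$data$censored_pct),
    sprintf("  LOQ: %g CFU/g (%.2f log10)", fit$data$loq, fit$loq_log10),
    sprintf("  mode: %s - %s", fit$data$mode, qn_note),
    sprintf("  mean: %.2f log10 CFU/g  (%d%% CI %.2f to %.2f)",
            fit$mu, round(100 * fit$level), fit$ci_mu[1], fit$ci_mu[2]),
    sprintf("  SD:   %.2f log10 CFU/g  (%d%% CI %.2f to %.2f)",
            fit$sigma, round(100 * fit$level),
            fit$ci_sigma[1], fit$ci_sigma[2]),
    sprintf("  5th percentile:  %.2f log10 CFU/g", fit$p05),
    sprintf("  95th percentile: %.2f log10 CFU/g", fit$p95),
    sprintf("  log-likelihood: %.4f  converged: %s  evaluations: %d",
            fit$loglik, fit$converged, fit$iterations))
}

#' Write the text and JSON reports plus the density-curve table
#'
#' @param fit An `"enum_fit"`.
#' @param out_prefix Path prefix; writes `<prefix>.txt`, `<prefix>.json`
#'   and `<prefix>_density.csv`.
#' @param input_path Optional provenance path, see [enum_report()].
#' @param grid_points Grid size for [density_table()].
#' @return Invisibly, the paths written.
#' @export
write_enum_report <- function(fit, out_prefix, input_path = NULL,
                              grid_points = 201) {
  paths <- paste0(out_prefix, c(".txt", ".json", "_density.csv"))
  writeLines(enum_report(fit, input_path, format = "text"), paths[1])
  writeLines(enum_report(fit, input_path, format = "json"), paths[2])
  if (isTRUE(fit$converged))
    utils::write.csv(density_table(fit, grid_points), paths[3],
                     row.names = FALSE)
  invisible(paths)
}
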