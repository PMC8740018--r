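#' @keywords internal
#' @noRd
new_enum_data <- function(observations, loq, label = "",
                          allow_all_censored = FALSE) {
  stopifnot(is.data.frame(observations),
            all(c("kind", "value", "lower", "upper", "weight") %in%
                  names(observations)))
  if (!is.numeric(loq) || length(loq) != 1L || !is.finite(loq) || loq <= 0)
    stop("'loq' must be a single positive finite concentration in CFU/g",
         call. = FALSE)
  obs <- observations
  # linear-scale columns are authoritative for serialisation; derive when
  # absent (e.g. datasets built directly from log10 draws)
  if (is.null(obs$lin_value)) obs$lin_value <- 10^obs$value
  if (is.null(obs$lin_lower)) obs$lin_lower <- 10^obs$lower
  if (is.null(obs$lin_upper)) obs$lin_upper <- 10^obs$upper
  obs$kind <- as.character(obs$kind)
  bad <- setdiff(unique(obs$kind), c("exact", "left_censored", "interval"))
  if (length(bad))
    stop("unknown observation kind: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (any(obs$weight < 1 | obs$weight != round(obs$weight)))
    stop("observation weights must be positive integers", call. = FALSE)
  ex <- obs$kind == "exact"
  if (any(ex & !is.finite(obs$value)))
    stop("exact observations require a finite log10 value", call. = FALSE)
  iv <- obs$kind == "interval"
  if (any(iv & !(obs$lower < obs$upper)))
    stop("interval observations require lower < upper", call. = FALSE)
  lc <- obs$kind == "left_censored"
  if (any(lc & abs(obs$upper - log10(loq)) > 1e-9))
    stop("left-censored observations must be bounded at log10(loq)",
         call. = FALSE)
  if (sum(obs$weight) < 1)
    stop("dataset is empty", call. = FALSE)
  if (!allow_all_censored && !any(obs$weight[!lc] > 0))
    stop(paste0("dataset is fully censored (100% ND): the lognormal ",
                "parameters are not identifiable from below-LOQ ",
                "observations alone"), call. = FALSE)
  mode <- enum_mode_for(any(lc), any(iv))
  structure(list(observations = obs, loq = loq, mode = mode, label = label),
            class = "enum_data")
}

# Sub-tool dispatch: censored present selects the MLE branch (QN_3/QN_4),
# interval data the semi-quantitative branch (QN_2/QN_4).
enum_mode_for <- function(has_censored, has_interval) {
  if (has_censored) {
    if (has_interval) "QN_4" else "QN_3"
  } else {
    if (has_interval) "QN_2" else "QN_1"
  }
}

#' Build an enumeration dataset from quantitative results
#'
#' Quantitative enumeration reports one concentration per sample, with
#' below-LOQ samples flagged "ND" (not detected).  Detected concentrations
#' become exact observations on the log10 scale; ND records become
#' left-censored observations bounded at `log10(loq)`.
#'
#' @param results Vector of results: positive concentrations in CFU/g, with
#'   ND samples given either as the string `"ND"` (case-insensitive) or as
#'   `NA`.  A numeric vector with `NA`s is accepted.
#' @param loq Limit of quantification in CFU/g (> 0); see [compute_loq()].
#' @param label Optional free-text label for reports.
#'
#' @return An object of class `"enum_data"` with mode `QN_3` if any ND
#'   record is present, else `QN_1`.
#' @examples
#' d <- enum_quantitative(c(20, "ND", 300), loq = 10)
#' censored_fraction(d)
#' @export
enum_quantitative <- function(results, loq, label = "") {
  if (length(results) < 1L) stop("no results supplied", call. = FALSE)
  if (is.character(results) || is.factor(results)) {
    tok <- trimws(as.character(results))
    nd <- toupper(tok) == "ND" | tok == ""
    val <- suppressWarnings(as.numeric(tok))
    if (any(!nd & is.na(val)))
      stop("unparseable result token(s): ",
           paste(unique(tok[!nd & is.na(val)]), collapse = ", "),
           call. = FALSE)
  } else if (is.numeric(results)) {
    nd <- is.na(results)
    val <- results
  } else stop("'results' must be numeric or character", call. = FALSE)
  det <- val[!nd]
  if (any(det <= 0))
    stop("detected concentrations must be positive", call. = FALSE)
  if (any(det < loq))
    stop("detected concentration below the LOQ (", loq,
         " CFU/g): inconsistent data entry", call. = FALSE)
  if (all(nd))
    stop(paste0("all results are ND: the dataset is fully censored and ",
                "the distribution is not identifiable"), call. = FALSE)
  obs <- NULL
  if (length(det))
    obs <- data.frame(kind = "exact", value = log10(det),
                      lower = NA_real_, upper = NA_real_,
                      lin_value = det, lin_lower = NA_real_,
                      lin_upper = NA_real_, weight = 1L)
  if (any(nd))
    obs <- rbind(obs,
                 data.frame(kind = "left_censored", value = NA_real_,
                            lower = NA_real_, upper = log10(loq),
                            lin_value = NA_real_, lin_lower = NA_real_,
                            lin_upper = loq, weight = sum(nd)))
  new_enum_data(obs, loq, label)
}

#' Build an enumeration dataset from interval (semi-quantitative) counts
#'
#' Semi-quantitative surveys report, per concentration class, the number of
#' samples falling in it, e.g. ND / 10--10^2 / 10^2--10^3 CFU/g.  Classes
#' are half-open `[lower, upper)` on the linear scale; the ND class is
#' `[0, loq)`.
#'
#' @param lower,upper Class bounds in CFU/g (linear scale); `lower >= loq`
#'   for every class.
#' @param count Number of samples per class (non-negative integers;
#'   zero-count classes are dropped).
#' @param nd Number of ND (below-LOQ) samples, default 0.
#' @param loq Limit of quantification in CFU/g.
#' @param label Optional free-text label.
#'
#' @return An `"enum_data"` object, mode `QN_4` if `nd > 0` else `QN_2`.
#' @examples
#' # decade classes 10..10^6 with 214 ND samples
#' d <- enum_intervals(lower = 10^(1:5), upper = 10^(2:6),
#'                     count = c(258, 368, 234, 44, 2), nd = 214, loq = 10)
#' censored_fraction(d)
#' @export
enum_intervals <- function(lower, upper, count, nd = 0, loq, label = "") {
  stopifnot(length(lower) == length(upper), length(lower) == length(count))
  if (any(count < 0 | count != round(count)) || nd < 0 || nd != round(nd))
    stop("counts must be non-negative integers", call. = FALSE)
  if (sum(count) == 0)
    stop("all class counts are zero: no detected observations", call. = FALSE)
  if (any(lower >= upper))
    stop("each class requires lower < upper", call. = FALSE)
  if (any(lower < loq - 1e-9))
    stop("class lower bound below the LOQ (", loq, " CFU/g)", call. = FALSE)
  o <- order(lower)
  lower <- lower[o]; upper <- upper[o]; count <- count[o]
  if (length(lower) > 1L &&
      any(lower[-1L] < upper[-length(upper)] - 1e-9))
    stop("concentration classes overlap", call. = FALSE)
  keep <- count > 0
  obs <- data.frame(kind = "interval", value = NA_real_,
                    lower = log10(lower[keep]), upper = log10(upper[keep]),
                    lin_value = NA_real_, lin_lower = lower[keep],
                    lin_upper = upper[keep],
                    weight = as.integer(count[keep]))
  if (nd > 0)
    obs <- rbind(obs,
                 data.frame(kind = "left_censored", value = NA_real_,
                            lower = NA_real_, upper = log10(loq),
                            lin_value = NA_real_, lin_lower = NA_real_,
                            lin_upper = loq, weight = as.integer(nd)))
  new_enum_data(obs, loq, label)
}

#' Counts of detected and censored observations
#'
#' @param x An `"enum_data"` object.
#' @return `n_detected()`: total weight of exact and interval observations;
#'   `m_censored()`: total weight of left-censored (ND) observations;
#'   `censored_fraction()`: `m / (n + m)` as an exact ratio.
#' @examples
#' d <- enum_quantitative(c(20, NA, 300), loq = 10)
#' n_detected(d); m_censored(d); censored_fraction(d)
#' @export
n_detected <- function(x) {
  stopifnot(inherits(x, "enum_data"))
  o <- x$observations
  sum(o$weight[o$kind != "left_censored"])
}

#' @rdname n_detected
#' @export
m_censored <- function(x) {
  stopifnot(inherits(x, "enum_data"))
  o <- x$observations
  sum(o$weight[o$kind == "left_censored"])
}

#' @rdname n_detected
#' @export
censored_fraction <- function(x) {
  n <- n_detected(x); m <- m_censored(x)
  if (n + m < 1) stop("empty dataset", call. = FALSE)
  m / (n + m)
}

#' @export
print.enum_data <- function(x, ...) {
  n <- n_detected(x); m <- m_censored(x)
  cat(sprintf("Microbial enumeration dataset%s [%s]\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              x$mode))
  cat(sprintf("  LOQ: %g CFU/g   detected: %d   ND (censored): %d (%.1f%%)\n",
              x$loq, n, m, 100 * m / (n + m)))
  o <- x$observations
  if (any(o$kind == "interval")) {
    iv <- o[o$kind == "interval", ]
    cat("  classes (log10 CFU/g):\n")
    for (i in seq_len(nrow(iv)))
      cat(sprintf("    [%.3g, %.3g): %d\n", iv$lower[i], iv$upper[i],
                  iv$weight[i]))
  }
  if (any(o$kind == "exact"))
    cat(sprintf("  exact log10 values: n = %d, range [%.2f, %.2f]\n",
                sum(o$weight[o$kind == "exact"]),
                min(o$value[o$kind == "exact"]),
                max(o$value[o$kind == "exact"])))
  invisible(x)
}
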