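#' Read and write enumeration CSV files
#'
#' Two CSV layouts are supported.  Dialect `"quantitative"` has a single
#' column `result` whose values are positive concentrations in CFU/g or the
#' token `ND`.  Dialect `"interval"` has columns `lower,upper,count` in
#' CFU/g, with the ND class given as a row whose `lower` field is the token
#' `ND` (its `upper` field is ignored and may be empty).  `"auto"` picks the
#' dialect from the header.
#'
#' @param path Path to the CSV file.
#' @param loq Limit of quantification in CFU/g.
#' @param dialect `"auto"`, `"quantitative"` or `"interval"`.
#' @param label Dataset label; defaults to the file name.
#' @return An `"enum_data"` object.
#' @examples
#' f <- system.file("extdata", "case1_total_coliforms.csv", package = "cfufit")
#' read_enum_csv(f, loq = 10)
#' @export
read_enum_csv <- function(path, loq,
                          dialect = c("auto", "quantitative", "interval"),
                          label = basename(path)) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, colClasses = "character",
                         strip.white = TRUE)
  if (dialect == "auto") {
    dialect <- if (all(c("lower", "upper", "count") %in% names(tab)))
      "interval"
    else if ("result" %in% names(tab)) "quantitative"
    else stop("cannot infer CSV dialect from header: ",
              paste(names(tab), collapse = ","), call. = FALSE)
  }
  if (dialect == "quantitative") {
    if (!"result" %in% names(tab))
      stop("quantitative dialect requires a 'result' column", call. = FALSE)
    enum_quantitative(tab$result, loq = loq, label = label)
  } else {
    if (!all(c("lower", "upper", "count") %in% names(tab)))
      stop("interval dialect requires columns lower,upper,count",
           call. = FALSE)
    is_nd <- toupper(tab$lower) == "ND"
    nd <- if (any(is_nd)) sum(as.numeric(tab$count[is_nd])) else 0
    det <- tab[!is_nd, , drop = FALSE]
    enum_intervals(lower = as.numeric(det$lower),
                   upper = as.numeric(det$upper),
                   count = as.numeric(det$count),
                   nd = nd, loq = loq, label = label)
  }
}

#' @rdname read_enum_csv
#' @param x An `"enum_data"` object to write.
#' @details `write_enum_csv()` chooses the dialect from the data: interval
#'   observations are written in the interval dialect, otherwise the
#'   quantitative dialect is used.  Round-tripping through
#'   `write_enum_csv()` / `read_enum_csv()` preserves observations, weights
#'   and the LOQ.
#' @export
write_enum_csv <- function(x, path) {
  stopifnot(inherits(x, "enum_data"))
  o <- x$observations
  if (any(o$kind == "interval")) {
    if (any(o$kind == "exact"))
      stop("cannot serialise a dataset mixing exact and interval ",
           "observations to a single CSV dialect", call. = FALSE)
    iv <- o[o$kind == "interval", ]
    rows <- data.frame(lower = sprintf("%.17g", iv$lin_lower),
                       upper = sprintf("%.17g", iv$lin_upper),
                       count = iv$weight)
    m <- sum(o$weight[o$kind == "left_censored"])
    if (m > 0)
      rows <- rbind(data.frame(lower = "ND", upper = "", count = m), rows)
    utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  } else {
    vals <- rep(sprintf("%.17g", o$lin_value[o$kind == "exact"]),
                o$weight[o$kind == "exact"])
    nd <- rep("ND", sum(o$weight[o$kind == "left_censored"]))
    utils::write.csv(data.frame(result = c(vals, nd)), path,
                     row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
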