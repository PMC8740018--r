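#' Describe a plating scheme
#'
#' A plating scheme records how a food sample was homogenised, diluted and
#' plated, which determines the limit of quantification (LOQ) of the
#' enumeration: the concentration corresponding to a single colony on the
#' plate at the lowest dilution examined.
#'
#' @param sample_mass Mass of the analysed sample in g (> 0).
#' @param diluent_volume Volume of diluent added to the sample in ml (> 0).
#' @param plated_volume Volume of homogenate spread on the plate in ml
#'   (> 0, default 1 ml, the usual pour-plate volume).
#' @param dilution_factor Additional serial dilution applied before
#'   plating, as a factor >= 1 (default 1, i.e. none).
#'
#' @return An object of class `"plating_scheme"`.
#' @seealso [compute_loq()]
#' @examples
#' ps <- plating_scheme(sample_mass = 25, diluent_volume = 225)
#' compute_loq(ps)  # 10 CFU/g
#' @export
plating_scheme <- function(sample_mass, diluent_volume, plated_volume = 1,
                           dilution_factor = 1) {
  for (nm in c("sample_mass", "diluent_volume", "plated_volume",
               "dilution_factor")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("'%s' must be a single positive finite number", nm),
           call. = FALSE)
  }
  if (dilution_factor < 1)
    stop("'dilution_factor' must be >= 1", call. = FALSE)
  structure(
    list(sample_mass = sample_mass, diluent_volume = diluent_volume,
         plated_volume = plated_volume, dilution_factor = dilution_factor),
    class = "plating_scheme"
  )
}

#' Limit of quantification of a plating scheme
#'
#' One colony on the plate corresponds to `1 / plated_volume` CFU per ml of
#' the plated dilution; multiplying back through the homogenate dilution
#' `(sample_mass + diluent_volume) / sample_mass` and any extra serial
#' dilution gives the lowest quantifiable concentration in CFU per g (or
#' ml) of the original sample.  The classical 1:10 homogenate (25 g in
#' 225 ml) with 1 ml plated gives LOQ = 10 CFU/g.
#'
#' @param scheme A [plating_scheme()].
#' @return The LOQ in CFU/g (or CFU/ml), a positive scalar.
#' @examples
#' compute_loq(plating_scheme(25, 225))          # 10
#' compute_loq(plating_scheme(10, 90, 1, 10))    # 100
#' @export
compute_loq <- function(scheme) {
  stopifnot(inherits(scheme, "plating_scheme"))
  (scheme$sample_mass + scheme$diluent_volume) / scheme$sample_mass *
    scheme$dilution_factor / scheme$plated_volume
}

#' @export
print.plating_scheme <- function(x, ...) {
  cat("Plating scheme\n")
  cat(sprintf("  sample mass:     %g g\n", x$sample_mass))
  cat(sprintf("  diluent volume:  %g ml\n", x$diluent_volume))
  cat(sprintf("  plated volume:   %g ml\n", x$plated_volume))
  cat(sprintf("  dilution factor: %g\n", x$dilution_factor))
  cat(sprintf("  LOQ:             %g CFU/g\n", compute_loq(x)))
  invisible(x)
}
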