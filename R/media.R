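# Growth media: specific growth rate, mass-doubling time, and the volume
# fraction inherited by the daughter cell at division.

.media_table <- list(
  glucose = list(
    name = "glucose", mu = 0.00700, f_daughter = 0.40, clb2_factor = 1.00
  ),
  galactose = list(
    name = "galactose", mu = 0.00467, f_daughter = 0.36, clb2_factor = 0.80
  ),
  `glycerol-ethanol` = list(
    name = "glycerol-ethanol", mu = 0.00398, f_daughter = 0.35,
    clb2_factor = 0.70
  )
)

#' Growth medium specification
#'
#' Returns the growth parameters for one of the three carbon sources used
#' throughout: the specific growth rate mu (min^-1), the derived mass
#' doubling time mdt = ln(2)/mu (min), and the fraction of cell volume
#' `f_daughter` that goes to the daughter at (asymmetric) division.
#' Mother:daughter volume ratios are 0.60:0.40 in glucose, 0.64:0.36 in
#' galactose and 0.65:0.35 in glycerol-ethanol.
#'
#' The entry also carries `clb2_factor`, a medium-indexed multiplier on the
#' CLB2 transcription rate: mitotic-cyclin synthesis falls with the specific
#' growth rate, which is what rescues certain stable-Clb2 mutants on poor
#' carbon sources.
#'
#' @param name one of `"glucose"`, `"galactose"`, `"glycerol-ethanol"`
#' @return an object of class `yc_medium`: a list with `name`, `mu`,
#'   `mdt`, `f_daughter`, `clb2_factor`
#' @examples
#' medium_growth("glucose")$mdt   # ~99 min
#' @export
medium_growth <- function(name) {
  if (!is.character(name) || length(name) != 1L || !name %in% names(.media_table)) {
    stop("unknown medium ", deparse(name), "; known media: ",
         paste(names(.media_table), collapse = ", "))
  }
  m <- .media_table[[name]]
  m$mdt <- log(2) / m$mu
  stopifnot(m$f_daughter > 0, m$f_daughter < 0.5)
  structure(m, class = "yc_medium")
}

#' @export
print.yc_medium <- function(x, ...) {
  cat(sprintf("medium '%s': mu = %.5f /min, MDT = %.1f min, f(daughter) = %.2f\n",
              x$name, x$mu, x$mdt, x$f_daughter))
  invisible(x)
}

#' Known growth media
#' @return character vector of medium names accepted by [medium_growth()]
#' @export
list_media <- function() names(.media_table)
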