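#' Convert a molecule count to a concentration
#'
#' Molecule numbers N in a cell of volume V (fL) are converted to
#' concentration C (nM) by C = 1.67 N / V, so that a concentration of
#' 100 nM in a 50 fL cell corresponds to roughly 3000 molecules.
#'
#' @param n molecule count (non-negative; need not be integer for
#'   deterministic states)
#' @param v cell volume in fL (> 0)
#' @param conv conversion constant in nM·fL per molecule (default 1.67)
#' @return concentration in nM
#' @seealso [conc_to_count()]
#' @export
count_to_conc <- function(n, v, conv = 1.67) {
  if (any(v <= 0)) stop("cell volume must be positive")
  if (any(n < 0)) stop("molecule counts must be non-negative")
  conv * n / v
}

#' Convert a concentration to a molecule count
#'
#' Inverse of [count_to_conc()]; the result is rounded to the nearest
#' integer molecule.
#'
#' @param c concentration in nM
#' @param v cell volume in fL (> 0)
#' @param conv conversion constant in nM·fL per molecule
#' @return integer molecule count
#' @export
conc_to_count <- function(c, v, conv = 1.67) {
  if (any(v <= 0)) stop("cell volume must be positive")
  round(c * v / conv)
}
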