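# One cell's instantaneous state.

#' Construct a cell state
#'
#' @param counts named vector of molecule counts over the network species
#' @param v cell volume (fL)
#' @param t absolute time (min)
#' @param bud_ss,dna_ss continuous indicator values (nM)
#' @param armed_division whether the division detector has been armed
#'   (free Clb2 concentration has exceeded the arming level since the last
#'   division)
#' @return list of class `yc_cell_state`
#' @export
cell_state <- function(counts, v = 30, t = 0, bud_ss = 0, dna_ss = 0,
                       armed_division = FALSE) {
  if (v <= 0) stop("cell volume must be positive")
  if (any(counts < 0)) stop("molecule counts must be non-negative")
  structure(list(counts = counts, v = v, t = t,
                 bud_ss = bud_ss, dna_ss = dna_ss,
                 armed_division = armed_division),
            class = "yc_cell_state")
}

#' Total molecule count of a protein across all its forms
#'
#' Sums free, phosphorylated and complex-bound forms, i.e. the total a
#' fluorescent antibody that does not distinguish phospho-epitopes would
#' see.
#'
#' @param net `yc_network` (supplies the membership map)
#' @param counts named count vector (or a matrix with species columns)
#' @param protein protein name, e.g. `"Whi5"`
#' @return summed count(s)
#' @export
protein_total <- function(net, counts, protein) {
  members <- net$index$totals[[protein]]
  if (is.null(members)) stop("unknown protein ", protein)
  if (is.matrix(counts)) rowSums(counts[, members, drop = FALSE])
  else sum(counts[members])
}
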