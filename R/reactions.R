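# Elementary-reaction representation shared by both simulation engines.
#
# A reaction has at most two reactant molecules. `rate` is the
# concentration-based rate constant; `mult` is a dimensionless
# combinatorial multiplicity (used by disordered phospho-chains); `scaling`
# says how the propensity depends on volume:
#   zero_order       a = rate*mult                  (per-gene-copy synthesis)
#   synthesis        a = rate*mult*V/conv           (volume-scaled zero order)
#   unimolecular     a = rate*mult*N1
#   bimolecular      a = rate*mult*N1*N2*conv/V     (N1*(N1-1)/2 if N1 == N2)
#   translation      a = rate*mult*N1*(V/v_ref)
#   cln3_translation a = rate*mult*N1*(V/v_ref)^2

.scaling_tags <- c("zero_order", "synthesis", "unimolecular", "bimolecular",
                   "translation", "cln3_translation")

#' Construct one elementary reaction
#'
#' @param reactants character vector of reactant species (length 0, 1 or 2;
#'   a homodimerization repeats the species)
#' @param products character vector of product species (may be empty)
#' @param rate concentration-based rate constant
#' @param scaling one of `"zero_order"`, `"synthesis"`, `"unimolecular"`,
#'   `"bimolecular"`, `"translation"`, `"cln3_translation"`
#' @param mult combinatorial multiplicity folded into the propensity
#' @param group free-text label for audit output
#' @return a list of class `yc_reaction`
#' @export
reaction <- function(reactants, products, rate, scaling, mult = 1,
                     group = "") {
  if (length(reactants) > 2L) stop("at most two reactant molecules allowed")
  scaling <- match.arg(scaling, .scaling_tags)
  need <- switch(scaling,
                 zero_order = 0L, synthesis = 0L,
                 unimolecular = 1L, translation = 1L, cln3_translation = 1L,
                 bimolecular = 2L)
  if (length(reactants) != need) {
    stop("scaling '", scaling, "' requires ", need, " reactant(s), got ",
         length(reactants))
  }
  if (rate < 0) stop("rate constant must be non-negative")
  structure(list(reactants = as.character(reactants),
                 products = as.character(products),
                 rate = rate, scaling = scaling, mult = mult, group = group),
            class = "yc_reaction")
}

# accumulate reactions efficiently during network generation
new_rxn_buffer <- function() {
  e <- new.env(parent = emptyenv())
  e$rxns <- vector("list", 256L)
  e$n <- 0L
  e
}

push_rxn <- function(buf, r) {
  buf$n <- buf$n + 1L
  if (buf$n > length(buf$rxns)) {
    buf$rxns <- c(buf$rxns, vector("list", length(buf$rxns)))
  }
  buf$rxns[[buf$n]] <- r
  invisible(buf)
}

rxn_list <- function(buf) buf$rxns[seq_len(buf$n)]

#' Tabulate a reaction list
#'
#' Flattens a list of reactions into a data frame (one row per reaction)
#' with `+`-joined reactant and product fields, suitable for TSV export and
#' audit.
#'
#' @param rxns list of `yc_reaction` objects (or a `yc_network`)
#' @return data.frame with columns `id`, `reactants`, `products`, `rate`,
#'   `mult`, `scaling`, `group`
#' @export
reaction_table <- function(rxns) {
  if (inherits(rxns, "yc_network")) rxns <- rxns$reactions
  data.frame(
    id = seq_along(rxns),
    reactants = vapply(rxns, function(r) paste(r$reactants, collapse = " + "),
                       ""),
    products = vapply(rxns, function(r) paste(r$products, collapse = " + "),
                      ""),
    rate = vapply(rxns, function(r) r$rate, 0),
    mult = vapply(rxns, function(r) r$mult, 0),
    scaling = vapply(rxns, function(r) r$scaling, ""),
    group = vapply(rxns, function(r) r$group, ""),
    stringsAsFactors = FALSE
  )
}
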