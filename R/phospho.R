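# Multisite phosphorylation chains: the ultrasensitivity-generating motif.

#' Define a multisite phosphorylation chain
#'
#' Eight proteins in the network are turned into ultrasensitive switches by
#' distributive multisite (de)phosphorylation. A chain is represented by
#' phospho-count species `<protein>_P0 ... _Pn`. For inactivation-type
#' proteins the forms with at most `m` phosphates are active
#' (`active_rule = "le_m"`); activation-type proteins are active only when
#' fully phosphorylated (`active_rule = "eq_n"`).
#'
#' @param protein species stem, e.g. `"Whi5"`
#' @param n_sites number of phosphorylation sites (>= 1)
#' @param m for `"le_m"` rules, the largest phospho-count that is still
#'   active (0 <= m < n)
#' @param active_rule `"le_m"` or `"eq_n"`
#' @param order_mode `"ordered"` (sites filled in a fixed order) or
#'   `"disordered"` (any site; count-resolved with combinatorial
#'   multiplicities)
#' @param kinases named numeric vector: kinase species -> rate constant
#'   (nM^-1 min^-1 per site)
#' @param phosphatases named numeric vector: phosphatase species -> rate
#'   constant
#' @return a list of class `yc_phospho_def`
#' @export
phospho_chain <- function(protein, n_sites, m = 0L,
                          active_rule = c("le_m", "eq_n"),
                          order_mode = c("ordered", "disordered"),
                          kinases = numeric(), phosphatases = numeric()) {
  active_rule <- match.arg(active_rule)
  order_mode <- match.arg(order_mode)
  if (n_sites < 1L) stop("n_sites must be >= 1")
  if (active_rule == "le_m" && (m < 0L || m >= n_sites)) {
    stop("inactivation rule requires 0 <= m < n")
  }
  structure(list(protein = protein, n_sites = as.integer(n_sites),
                 m = as.integer(m), active_rule = active_rule,
                 order_mode = order_mode, kinases = kinases,
                 phosphatases = phosphatases),
            class = "yc_phospho_def")
}

#' Names of the phospho-count species of a chain
#' @param def a [phospho_chain()] definition
#' @return character vector `<protein>_P0 ... <protein>_Pn`
#' @export
phospho_species <- function(def) {
  paste0(def$protein, "_P", 0:def$n_sites)
}

#' Expand a phosphorylation chain into species and elementary reactions
#'
#' Ordered mode emits, per kinase, one phosphorylation reaction out of each
#' of the n non-terminal states (and symmetrically for phosphatases), i.e.
#' 2n reactions per kinase/phosphatase pair. Disordered mode emits the same
#' n+1 count-resolved species but weights phosphorylation out of state k by
#' the number of free sites (n-k) and dephosphorylation by the number of
#' occupied sites (k); under site-symmetric rates this is exactly the
#' marginal of the 2^n site-resolved master equation.
#'
#' @param def a [phospho_chain()] definition
#' @return list with `species` (character), `reactions` (list of
#'   [reaction()]s) and `active` (logical mask over the species, marking
#'   which phospho-forms count as active)
#' @export
expand_phospho_chain <- function(def) {
  stopifnot(inherits(def, "yc_phospho_def"))
  n <- def$n_sites
  if (n == 0L && length(def$kinases))
    stop("a chain with zero sites cannot have kinases")
  sp <- phospho_species(def)
  buf <- new_rxn_buffer()
  grp <- paste0("phospho:", def$protein)
  for (kin in names(def$kinases)) {
    kcat <- def$kinases[[kin]]
    for (k in 0:(n - 1L)) {
      mult <- if (def$order_mode == "disordered") n - k else 1
      push_rxn(buf, reaction(c(sp[k + 1L], kin), c(sp[k + 2L], kin),
                             kcat, "bimolecular", mult = mult, group = grp))
    }
  }
  for (ph in names(def$phosphatases)) {
    kcat <- def$phosphatases[[ph]]
    for (k in 1:n) {
      mult <- if (def$order_mode == "disordered") k else 1
      push_rxn(buf, reaction(c(sp[k + 1L], ph), c(sp[k], ph),
                             kcat, "bimolecular", mult = mult, group = grp))
    }
  }
  active <- if (def$active_rule == "le_m") (0:n) <= def$m else (0:n) == n
  names(active) <- sp
  list(species = sp, reactions = rxn_list(buf), active = active)
}

#' APC:Cdc20 affinity ladder
#'
#' The anaphase-promoting complex is phosphorylated on 11 sites; the more
#' phosphorylated it is, the more strongly it binds Cdc20. The association
#' rate for the form with k phosphates is multiplied by beta^(n-k) with
#' beta = 0.525, n = 11, so the fully phosphorylated APC binds at the full
#' rate and the unphosphorylated form is ~870-fold slower. All Cdc20:APC
#' complexes have equal catalytic potency once formed.
#'
#' @param k phospho-count of the APC (0..n)
#' @param params parameter set (uses `beta_apc` and `n_apc`)
#' @return dimensionless multiplier beta^(n-k)
#' @export
apc_affinity_factor <- function(k, params = default_params()) {
  n <- params$n_apc
  if (any(k < 0) || any(k > n)) stop("APC phospho-count must lie in 0..", n)
  params$beta_apc^(n - k)
}
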