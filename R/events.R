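# Scoring of cell-cycle milestones from states and trajectories.
#
# The stochastic core scores these on-line (at its 0.1-min null-event
# cadence); the functions here are the reference implementations used on
# stored trajectories and in tests. Event detectors are invariant to the
# sampling cadence up to one sampling interval.

#' Advance the continuous indicator variables
#'
#' The budding indicator relaxes with first-order kinetics toward
#' (ks/kd) times an efficiency-weighted sum of cyclin concentrations
#' (all G1 and S cyclins contribute); the DNA-synthesis indicator likewise,
#' but only B-type cyclins contribute. Both reset to zero at division in
#' both progeny.
#'
#' @param net a `yc_network`
#' @param state a [cell_state()]
#' @param dt time step (min, > 0)
#' @return the state with `bud_ss`, `dna_ss` advanced by `dt` (exact
#'   exponential relaxation at frozen cyclin levels)
#' @export
update_indicators <- function(net, state, dt) {
  if (dt <= 0) stop("dt must be positive")
  p <- net$params
  idx <- net$index
  conc <- function(w) {
    sum(w * state$counts[names(w)]) * p$conv / state$v
  }
  tgt_b <- p$ks_bud * conc(idx$bud_weights) / p$kd_bud
  tgt_d <- p$ks_dna * conc(idx$dna_weights) / p$kd_dna
  state$bud_ss <- tgt_b + (state$bud_ss - tgt_b) * exp(-p$kd_bud * dt)
  state$dna_ss <- tgt_d + (state$dna_ss - tgt_d) * exp(-p$kd_dna * dt)
  state
}

#' Detect division events on a Clb2 concentration series
#'
#' A division fires on a downward crossing of the division threshold, but
#' only when the detector is armed, i.e. the concentration has exceeded the
#' arming level (2x the threshold) since birth or the previous division.
#' Arming prevents newborn G1 cells, whose Clb2 is already low, from
#' re-triggering. The detector disarms after firing.
#'
#' @param time time grid
#' @param clb2 free Clb2 concentration series (nM)
#' @param threshold division threshold (nM)
#' @param arm_level arming level (nM)
#' @param armed initial arming state
#' @return numeric vector of division times
#' @export
detect_division <- function(time, clb2, threshold = 12.5,
                            arm_level = 2 * threshold, armed = FALSE) {
  stopifnot(length(time) == length(clb2))
  out <- numeric()
  for (i in seq_along(clb2)) {
    if (!armed && clb2[i] >= arm_level) {
      armed <- TRUE
    } else if (armed && clb2[i] < threshold) {
      out <- c(out, time[i])
      armed <- FALSE
    }
  }
  out
}

#' Nuclear Whi5 concentration of a state
#'
#' Sums all Whi5-containing species with 0, 1 or 2 phosphate groups --
#' free or SBF-bound, the forms capable of binding SBF -- and converts to
#' nM. Whi5 is scored as having left the nucleus when this concentration
#' first drops below the 200 nM threshold.
#'
#' @param net a `yc_network`
#' @param counts named count vector (or matrix with species columns)
#' @param v cell volume (fL), vector-compatible with `counts`
#' @return concentration (nM)
#' @export
whi5_nuclear <- function(net, counts, v) {
  members <- net$index$whi5_nuclear
  n <- if (is.matrix(counts)) rowSums(counts[, members, drop = FALSE])
       else sum(counts[members])
  count_to_conc(n, v, net$params$conv)
}

#' First upward crossing ages of gene activities
#'
#' Given per-gene activity series (fractional promoter occupancy, smoothed
#' for stochastic runs), returns the first time each series rises through
#' its threshold; `NA` when it never does.
#'
#' @param time time grid (ages since birth)
#' @param activity matrix or data.frame of activity series (columns =
#'   genes)
#' @param thresholds named thresholds per column
#' @return named numeric vector of activation ages (`NA` if absent)
#' @export
gene_activation_times <- function(time, activity, thresholds) {
  activity <- as.matrix(activity)
  out <- stats::setNames(rep(NA_real_, ncol(activity)), colnames(activity))
  for (g in colnames(activity)) {
    th <- thresholds[[g]]
    i <- which(activity[, g] >= th)
    if (length(i)) out[g] <- time[i[1]]
  }
  out
}

#' Classify the arrest phase of a non-dividing cell
#'
#' A cell that has not divided within the arrest window is classified by
#' the furthest milestone it reached: `unbudded` if the budding indicator
#' never crossed, `unreplicated` if budded but DNA synthesis never started,
#' `m_phase` if replicated but never divided. Dividing cells get `none`.
#' The labels partition non-dividing cells: exactly one applies.
#'
#' @param divided did the cell divide within the window?
#' @param budded did `bud_ss` cross its threshold?
#' @param dna_done did `dna_ss` cross its threshold?
#' @return one of `"none"`, `"unbudded"`, `"unreplicated"`, `"m_phase"`
#' @export
classify_arrest <- function(divided, budded, dna_done) {
  if (divided) "none"
  else if (!budded) "unbudded"
  else if (!dna_done) "unreplicated"
  else "m_phase"
}

#' Arrest fractions of a lineage table
#'
#' @param table a `yc_lineage`
#' @return named proportions over `none` / `unbudded` / `unreplicated` /
#'   `m_phase`
#' @export
arrest_fractions <- function(table) {
  lv <- c("none", "unbudded", "unreplicated", "m_phase")
  tab <- table(factor(table$arrest, levels = lv))
  tab / sum(tab)
}
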