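# Deterministic engine: mass-action ODEs in molecule-number units.
#
# The state is integrated in numbers (dN/dt = sum over reactions of
# stoichiometry x mean-field propensity), with dV/dt = mu*V, so growth
# dilution enters through the volume-scaled rates exactly as in the
# stochastic engine -- there is no separate -mu*C term. Concentrations are
# derived for reporting. Division is symmetric: when the free Clb2
# concentration falls through the division threshold (after having been
# armed above the arming level), V and every species population are halved.

#' Mass-action time-derivatives of a network state
#'
#' @param net a `yc_network` (or an already [compile_network()]-ed one)
#' @param state a [cell_state()]
#' @return list with `dcounts` (named, molecules/min), `dv` (fL/min),
#'   `dbud_ss`, `ddna_ss` (nM/min)
#' @export
derivatives <- function(net, state) {
  cnet <- if (!is.null(net$S)) net else compile_network(net)
  a <- propensities_all(cnet, state$counts, state$v)
  dc <- drop(a %*% cnet$S)
  names(dc) <- cnet$species
  ind <- indicator_rates(cnet, state$counts, state$v,
                         state$bud_ss, state$dna_ss)
  list(dcounts = dc, dv = cnet$medium$mu * state$v,
       dbud_ss = ind[["bud"]], ddna_ss = ind[["dna"]])
}

# first-order relaxation rates of the two indicator variables (nM/min)
indicator_rates <- function(cnet, counts, v, bud_ss, dna_ss) {
  p <- cnet$params
  idx <- cnet$index
  if (is.null(idx)) return(c(bud = 0, dna = 0))
  conc <- function(w) {
    sum(w * counts[names(w)]) * p$conv / v
  }
  c(bud = unname(p$ks_bud * conc(idx$bud_weights) - p$kd_bud * bud_ss),
    dna = unname(p$ks_dna * conc(idx$dna_weights) - p$kd_dna * dna_ss))
}

#' Deterministic simulation with event detection and symmetric division
#'
#' Integrates the mass-action ODEs (deSolve `lsodar`, adaptive stiff
#' integration with root finding) from `init` to `t_end`. The division
#' detector arms when free [Clb2] rises through the arming level and fires
#' on the subsequent downward crossing of the division threshold; at each
#' division V and all species populations are halved and the indicator
#' variables reset. Budding, DNA-synthesis onset and Whi5 nuclear exit are
#' scored from the dense output.
#'
#' @param net a `yc_network`
#' @param init optional [cell_state()]; defaults to the network's initial
#'   state at 30 fL
#' @param t_end end time (min)
#' @param dt_out output grid spacing (min)
#' @param rtol,atol integration tolerances
#' @return object of class `yc_ode_trajectory`: list with `time`, `counts`
#'   (matrix), `v`, `bud_ss`, `dna_ss`, `divisions` (times), `events`
#'   (data.frame), plus the network
#' @export
simulate_deterministic <- function(net, init = NULL, t_end = 600,
                                   dt_out = 0.5, rtol = 1e-6, atol = 1e-3) {
  cnet <- compile_network(net)
  p <- net$params
  if (is.null(init)) init <- cell_state(net$init, v = 30, t = 0)
  if (t_end <= init$t) stop("t_end must exceed the initial time")
  nsp <- length(cnet$species)
  has_div <- !is.null(net$index$clb2_free)
  iclb2 <- if (has_div) match(net$index$clb2_free, cnet$species) else NA_integer_

  rhs <- function(t, y, parms) {
    counts <- y[seq_len(nsp)]
    v <- y[nsp + 1]
    a <- propensities_all(cnet, counts, v)
    dc <- drop(a %*% cnet$S)
    ind <- indicator_rates(cnet, counts, v, y[nsp + 2], y[nsp + 3])
    list(c(dc, cnet$medium$mu * v, ind[["bud"]], ind[["dna"]]))
  }
  # root 1: arming level; root 2: division threshold (handled when armed)
  rootfun <- function(t, y, parms) {
    cl <- p$conv * y[iclb2] / y[nsp + 1]
    c(cl - p$th_arm, cl - p$th_div)
  }

  y <- c(init$counts, V = init$v, bud_ss = init$bud_ss, dna_ss = init$dna_ss)
  t0 <- init$t
  armed <- init$armed_division
  divisions <- numeric()
  out_all <- NULL
  while (t0 < t_end - 1e-9) {
    times <- unique(c(t0, seq(ceiling(t0 / dt_out) * dt_out, t_end,
                              by = dt_out), t_end))
    sol <- if (has_div) {
      deSolve::lsodar(y, times, rhs, parms = NULL, rootfunc = rootfun,
                      rtol = rtol, atol = atol, maxsteps = 50000)
    } else {
      deSolve::lsoda(y, times, rhs, parms = NULL,
                     rtol = rtol, atol = atol, maxsteps = 50000)
    }
    out_all <- rbind(out_all, sol[-1, , drop = FALSE])
    t_last <- sol[nrow(sol), 1]
    y <- sol[nrow(sol), -1]
    if (t_last >= t_end - 1e-9) break
    # a root was hit: classify by current Clb2 concentration and slope
    cl <- p$conv * y[iclb2] / y[nsp + 1]
    d <- rhs(t_last, y, NULL)[[1]]
    dcl <- p$conv * (d[iclb2] / y[nsp + 1] -
                       y[iclb2] * d[nsp + 1] / y[nsp + 1]^2)
    if (abs(cl - p$th_arm) < abs(cl - p$th_div)) {
      if (dcl > 0) armed <- TRUE
    } else if (armed && dcl < 0) {
      divisions <- c(divisions, t_last)
      # equal partition of molecules; the (haploid) gene copies are not
      # molecules to be split -- each progeny keeps the genome, so
      # promoter-state variables are carried over unchanged
      mol <- net$species$role != "promoter"
      y[seq_len(nsp)][mol] <- y[seq_len(nsp)][mol] / 2
      y[nsp + 1] <- y[nsp + 1] / 2
      y[nsp + 2] <- 0
      y[nsp + 3] <- 0
      armed <- FALSE
    }
    t0 <- t_last + 1e-6
  }

  colnames(out_all) <- c("time", cnet$species, "V", "bud_ss", "dna_ss")
  traj <- structure(list(
    time = out_all[, "time"],
    counts = out_all[, cnet$species, drop = FALSE],
    v = out_all[, "V"],
    bud_ss = out_all[, "bud_ss"],
    dna_ss = out_all[, "dna_ss"],
    divisions = divisions,
    network = net
  ), class = "yc_ode_trajectory")
  traj$events <- ode_trajectory_events(traj)
  traj
}

# score budding / DNA onset / Whi5 exit on the dense output grid
ode_trajectory_events <- function(traj) {
  if (is.null(traj$network$index)) {
    return(data.frame(event = character(), t = numeric()))
  }
  p <- traj$network$params
  up <- function(x, th) {
    i <- which(x[-1] >= th & x[-length(x)] < th)
    if (length(i)) traj$time[i + 1] else numeric()
  }
  whi5 <- count_to_conc(
    rowSums(traj$counts[, traj$network$index$whi5_nuclear, drop = FALSE]),
    traj$v, p$conv)
  down <- which(whi5[-1] < p$th_whi5 & whi5[-length(whi5)] >= p$th_whi5)
  ev <- function(name, t) {
    if (length(t)) data.frame(event = name, t = t) else NULL
  }
  out <- rbind(
    ev("budding", up(traj$bud_ss, p$th_bud)),
    ev("dna_onset", up(traj$dna_ss, p$th_dna)),
    ev("whi5_exit", if (length(down)) traj$time[down + 1] else numeric()),
    ev("division", traj$divisions)
  )
  if (is.null(out)) data.frame(event = character(), t = numeric()) else out
}

#' Concentration series from an ODE trajectory
#'
#' @param traj a `yc_ode_trajectory`
#' @param species species name (a column of the count matrix) or a protein
#'   name resolved through the network's totals map when `total = TRUE`
#' @param total sum all forms of the protein
#' @return numeric vector of concentrations (nM) on the trajectory grid
#' @export
trajectory_conc <- function(traj, species, total = FALSE) {
  n <- if (total) protein_total(traj$network, traj$counts, species)
       else traj$counts[, species]
  count_to_conc(n, traj$v, traj$network$params$conv)
}

#' Converged-cycle summary of a deterministic run
#'
#' Division-to-division periods and, over the last full cycle, per-species
#' min/max counts.
#'
#' @param traj a `yc_ode_trajectory`
#' @return list with `periods` (successive interdivision times) and
#'   `last_cycle` (data.frame of species min/max)
#' @export
ode_cycle_summary <- function(traj) {
  dv <- traj$divisions
  periods <- diff(dv)
  last_cycle <- NULL
  if (length(dv) >= 2) {
    sel <- traj$time > dv[length(dv) - 1] & traj$time <= dv[length(dv)]
    m <- traj$counts[sel, , drop = FALSE]
    last_cycle <- data.frame(species = colnames(m),
                             min = apply(m, 2, min), max = apply(m, 2, max),
                             row.names = NULL)
  }
  list(periods = periods, last_cycle = last_cycle)
}
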