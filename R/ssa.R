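# R-side wrapper of the stochastic simulation core.

#' Prepare a network for repeated stochastic simulation
#'
#' Flattens the compiled network into the index arrays consumed by the C++
#' core (sparse stoichiometry, propensity dependency graph, event-scoring
#' indices). The result can be reused across many cells of a culture.
#'
#' @param net a `yc_network`
#' @return list of class `yc_ssa_ready`
#' @export
ssa_compile <- function(net) {
  cnet <- compile_network(net)
  nr <- length(cnet$rate)
  sp_idx <- integer(); sp_val <- numeric(); sp_ptr <- integer(nr + 1)
  for (i in seq_len(nr)) {
    ch <- which(cnet$S[i, ] != 0)
    sp_ptr[i + 1] <- sp_ptr[i] + length(ch)
    sp_idx <- c(sp_idx, ch)
    sp_val <- c(sp_val, cnet$S[i, ch])
  }
  dep_idx <- integer(); dep_ptr <- integer(nr + 1)
  for (i in seq_len(nr)) {
    d <- cnet$dep_rxn[[i]]
    dep_ptr[i + 1] <- dep_ptr[i] + length(d)
    dep_idx <- c(dep_idx, d)
  }
  structure(list(
    arrays = list(r1 = cnet$r1, r2 = cnet$r2, scode = cnet$scode,
                  rate = cnet$rate, sp_ptr = sp_ptr, sp_idx = sp_idx,
                  sp_val = sp_val, dep_ptr = dep_ptr, dep_idx = dep_idx),
    species = cnet$species, params = cnet$params, medium = cnet$medium,
    index = cnet$index, network = net
  ), class = "yc_ssa_ready")
}

# assemble the option list for the C++ core
.ssa_opts <- function(ready, init, sample_dt, sample_species,
                      stop_at_division, dt_null,
                      activity = c("occupancy", "window")) {
  activity <- match.arg(activity)
  p <- ready$params
  sp <- ready$species
  idx <- ready$index
  m <- function(x) match(x, sp)
  has_model_events <- !is.null(idx$clb2_free)
  sample_idx <- if (is.null(sample_species)) seq_along(sp)
                else m(sample_species)
  list(
    conv = p$conv, v_ref = p$v_ref, dt_null = dt_null,
    iclb2 = if (has_model_events) m(idx$clb2_free) else 0L,
    whi5_idx = if (has_model_events) m(idx$whi5_nuclear) else integer(),
    bud_i = if (has_model_events) m(names(idx$bud_weights)) else integer(),
    bud_w = if (has_model_events) unname(idx$bud_weights) else numeric(),
    dna_i = if (has_model_events) m(names(idx$dna_weights)) else integer(),
    dna_w = if (has_model_events) unname(idx$dna_weights) else numeric(),
    ks_bud = p$ks_bud %||% 0, kd_bud = p$kd_bud %||% 1,
    ks_dna = p$ks_dna %||% 0, kd_dna = p$kd_dna %||% 1,
    th_div = p$th_div %||% Inf, th_arm = p$th_arm %||% Inf,
    th_bud = p$th_bud %||% Inf, th_dna = p$th_dna %||% Inf,
    th_whi5 = p$th_whi5 %||% Inf,
    act_idx = if (has_model_events) unname(m(idx$act_promoters)) else integer(),
    act_th = if (has_model_events) {
      unname(c(p$th_act_cln2, p$th_act_rad27, p$th_act_clb2))
    } else numeric(),
    act_window = 100L,  # 10 min of 0.1-min samples (window mode)
    act_occupancy = activity == "occupancy",
    act_tf_ptr = if (has_model_events) c(0L, 1L, 5L, 6L) else integer(1),
    act_tf_idx = if (has_model_events) {
      m(c("SBF_P0", "Cln1", "Cln2", "Cln3", "Clb5", "Fkh2_P2"))
    } else integer(),
    act_tf_w = if (has_model_events) {
      c(p$kon_CLN2,
        p$kon_RAD27 * c(p$w_rad27_cln1, p$w_rad27_cln2, p$w_rad27_cln3,
                        p$w_rad27_clb5),
        p$kon_CLB2)
    } else numeric(),
    act_koff = if (has_model_events) {
      c(p$koff_CLN2, p$koff_RAD27, p$koff_CLB2)
    } else numeric(),
    act_ema_rate = 1,  # 1-min smoothing of the occupancy signal
    stop_at_division = stop_at_division,
    sample_dt = sample_dt, sample_idx = sample_idx,
    budded = FALSE, dna_done = FALSE,
    armed = isTRUE(init$armed_division),
    bud_ss = init$bud_ss, dna_ss = init$dna_ss
  )
}

#' Stochastic simulation of one cell
#'
#' Runs the exact SSA (direct method) from the given state until `t_end` or
#' until the cell divides (downward crossing of free [Clb2] through the
#' division threshold after arming). Identical `(net, init, t_end, seed,
#' cell_id)` give bit-identical results; each cell draws from its own
#' counter-based stream derived from `(seed, cell_id)`, so culture runs are
#' reproducible regardless of scheduling order.
#'
#' @param net a `yc_network` or a pre-compiled [ssa_compile()] object
#' @param init a [cell_state()]; defaults to the network's initial state
#' @param t_end absolute stop time (min)
#' @param seed master seed (integer)
#' @param cell_id cell identifier mixed into the seed
#' @param sample_dt if > 0, sample the trajectory at this cadence (min)
#' @param sample_species species to record (default all)
#' @param stop_at_division stop at the first division event
#' @param dt_null spacing of forced null events bounding the
#'   constant-volume approximation (min)
#' @param activity gene-activity scoring mode: `"occupancy"` (default; the
#'   promoter-occupancy function of instantaneous transcription-factor
#'   concentrations, smoothed with a 1-min EMA) or `"window"` (1-min-scale
#'   sliding-window mean of the binary promoter state)
#' @return object of class `yc_trajectory`: final [cell_state()], absolute
#'   event times (`t_bud`, `t_dna`, `t_whi5`, `t_div`, `t_act` per tracked
#'   gene), `n_events`, and optionally a sampled `trajectory` matrix with
#'   columns `t`, `V`, `bud_ss`, `dna_ss` and the sampled species
#' @export
simulate_cell <- function(net, init = NULL, t_end = 500, seed = 1,
                          cell_id = 1, sample_dt = 0, sample_species = NULL,
                          stop_at_division = TRUE, dt_null = 0.1,
                          activity = c("occupancy", "window")) {
  ready <- if (inherits(net, "yc_ssa_ready")) net else ssa_compile(net)
  if (is.null(init)) {
    init <- cell_state(ready$network$init, v = 30, t = 0)
  }
  if (t_end <= init$t) stop("t_end must exceed the initial time")
  counts <- init$counts[ready$species]
  if (anyNA(counts)) stop("initial state is missing species")
  opts <- .ssa_opts(ready, init, sample_dt, sample_species,
                    stop_at_division, dt_null, activity)
  res <- .ssa_run(ready$arrays, unname(counts), init$v, init$t, t_end,
                  ready$medium$mu, opts, as.double(seed), as.double(cell_id))
  counts_out <- stats::setNames(res$counts, ready$species)
  tr <- res$trajectory
  if (length(tr)) {
    colnames(tr) <- c("t", "V", "bud_ss", "dna_ss",
                      ready$species[opts$sample_idx])
  } else tr <- NULL
  structure(list(
    state = cell_state(counts_out, v = res$v, t = res$t,
                       bud_ss = res$bud_ss, dna_ss = res$dna_ss,
                       armed_division = res$armed),
    t_bud = res$t_bud, t_dna = res$t_dna, t_whi5 = res$t_whi5,
    t_div = res$t_div,
    t_act = stats::setNames(res$t_act, names(ready$index$act_promoters)),
    n_events = res$n_events, exhausted = res$exhausted,
    trajectory = tr, t_birth = init$t, v_birth = init$v
  ), class = "yc_trajectory")
}

#' Write a sampled trajectory to TSV
#'
#' @param traj a `yc_trajectory` (with a sampled trajectory) or
#'   `yc_ode_trajectory`
#' @param path output file
#' @param species optional subset of species columns
#' @return the path, invisibly
#' @export
write_trajectory_tsv <- function(traj, path, species = NULL) {
  if (inherits(traj, "yc_ode_trajectory")) {
    m <- cbind(t = traj$time, V = traj$v, bud_ss = traj$bud_ss,
               dna_ss = traj$dna_ss, traj$counts)
  } else {
    m <- traj$trajectory
    if (is.null(m)) stop("trajectory was not sampled (sample_dt = 0)")
  }
  if (!is.null(species)) {
    m <- m[, c("t", "V", "bud_ss", "dna_ss", species), drop = FALSE]
  }
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
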