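# "Computational culture": birth-ordered scheduling of asymmetrically
# dividing cells with full pedigree records.

#' Culture configuration
#'
#' @param max_cells stop after this many completed (divided or arrested)
#'   cells
#' @param t_stop stop scheduling cells born after this time (min; Inf to
#'   rely on `max_cells`)
#' @param seed master seed; every cell's SSA stream and every division draw
#'   derive from it
#' @param partition `"proportional"` (deterministic f-fraction, rounded) or
#'   `"binomial"` (each molecule independently daughter-bound with
#'   probability f) partitioning of molecules at division
#' @param f_cv coefficient of variation of Gaussian noise on the daughter
#'   volume fraction f (0 = deterministic f; draws truncated to
#'   (0.05, 0.95) by resampling)
#' @param arrest_window minutes a cell may run without dividing before
#'   being classified as arrested
#' @param sample_dt per-cell trajectory sampling cadence (0 = none)
#' @param sample_species species recorded when `sample_dt > 0`
#' @return list of class `yc_culture_config`
#' @export
culture_config <- function(max_cells = 50, t_stop = Inf, seed = 1,
                           partition = c("proportional", "binomial"),
                           f_cv = 0, arrest_window = NULL,
                           sample_dt = 0, sample_species = NULL) {
  partition <- match.arg(partition)
  if (max_cells <= 0) stop("max_cells must be positive")
  structure(list(max_cells = max_cells, t_stop = t_stop, seed = seed,
                 partition = partition, f_cv = f_cv,
                 arrest_window = arrest_window,
                 sample_dt = sample_dt, sample_species = sample_species),
            class = "yc_culture_config")
}

#' Divide a cell into mother and daughter
#'
#' Volumes split (1-f)V to the mother and fV to the daughter. Molecules are
#' partitioned per species: in proportional mode the daughter receives
#' round(f*N) (round half up), in binomial mode Binomial(N, f) draws; the
#' mother gets the remainder, so totals are conserved exactly. Cln3 is the
#' exception: only 25% goes to the daughter (p = 0.25 in binomial mode),
#' reflecting the daughter-specific Start delay. The haploid gene-copy
#' (promoter-state) species are not molecules to split: both progeny
#' inherit the genome, in the state it was in at division. Indicators and
#' the division detector reset in both progeny.
#'
#' @param net the `yc_network` (provides species roles and the Cln3 index)
#' @param state the dividing cell's [cell_state()]
#' @param f fraction of volume to the daughter (0 < f < 1)
#' @param mode `"proportional"` or `"binomial"`
#' @return list with `mother` and `daughter` cell states
#' @export
divide_cell <- function(net, state, f, mode = c("proportional", "binomial")) {
  mode <- match.arg(mode)
  if (f <= 0 || f >= 1) stop("daughter fraction f must lie in (0, 1)")
  n <- state$counts
  is_prom <- net$species$role == "promoter"
  names(is_prom) <- net$species$name
  frac <- rep(f, length(n))
  names(frac) <- names(n)
  if ("Cln3" %in% names(frac)) frac["Cln3"] <- 0.25
  daughter <- if (mode == "proportional") {
    floor(frac * n + 0.5)
  } else {
    stats::setNames(stats::rbinom(length(n), as.integer(round(n)), frac),
                    names(n))
  }
  daughter <- pmin(daughter, n)
  mother <- n - daughter
  daughter[is_prom] <- n[is_prom]
  mother[is_prom] <- n[is_prom]
  list(
    mother = cell_state(mother, v = (1 - f) * state$v, t = state$t),
    daughter = cell_state(daughter, v = f * state$v, t = state$t)
  )
}

# derived integer seed < 2^31 for division randomness
.div_seed <- function(master, id) {
  as.integer((as.double(master) * 48271 + as.double(id) * 16807) %% 2147483647)
}

#' Grow a computational culture
#'
#' Starts from one founder cell at the network's initial state and follows
#' the published scheduling rule: take the cell with the earliest birth
#' time, simulate its full cycle (birth to division, or to the arrest
#' window), then append its mother/daughter progeny to the list with their
#' recorded birth times. Every cell's randomness derives from (master
#' seed, cell id), so the run is reproducible.
#'
#' @param net a `yc_network`
#' @param config a [culture_config()]
#' @return object of class `yc_lineage`: a data.frame of per-cell records
#'   (pedigree, birth/division times and volumes, event ages, arrest
#'   label), with the config and network attached as attributes; when
#'   `sample_dt > 0` the per-cell trajectories are in
#'   `attr(x, "trajectories")`
#' @export
run_culture <- function(net, config = culture_config()) {
  ready <- ssa_compile(net)
  p <- net$params
  # default window: 500 min, stretched on slow media so that the long
  # (but finite) G1 tail of tiny daughters is not misread as arrest
  window <- config$arrest_window %||% max(p$arrest_window,
                                          3.5 * net$medium$mdt)
  f_base <- net$medium$f_daughter
  founder <- cell_state(net$init, v = 30, t = 0)
  pending <- list(list(id = 1L, parent = NA_integer_, md = "founder",
                       state = founder))
  births <- 0
  rows <- list()
  trajs <- list()
  next_id <- 2L
  n_done <- 0L
  while (length(pending) && n_done < config$max_cells) {
    k <- which.min(vapply(pending, function(c) c$state$t, 0))
    cell <- pending[[k]]
    pending[[k]] <- NULL
    t_birth <- cell$state$t
    if (t_birth > config$t_stop) break
    sim <- simulate_cell(ready, init = cell$state,
                         t_end = t_birth + window + 1,
                         seed = config$seed, cell_id = cell$id,
                         sample_dt = config$sample_dt,
                         sample_species = config$sample_species,
                         stop_at_division = TRUE)
    if (config$sample_dt > 0) trajs[[as.character(cell$id)]] <- sim$trajectory
    divided <- !is.na(sim$t_div) && (sim$t_div - t_birth) <= window
    arrest <- if (divided) {
      "none"
    } else if (is.na(sim$t_bud)) {
      "unbudded"
    } else if (is.na(sim$t_dna)) {
      "unreplicated"
    } else "m_phase"
    age <- function(t_abs) if (is.na(t_abs)) NA_real_ else t_abs - t_birth
    T_div <- if (divided) sim$t_div - t_birth else NA_real_
    T_unbud <- age(sim$t_bud)
    T_g1 <- age(sim$t_dna)
    mu <- net$medium$mu
    rows[[length(rows) + 1L]] <- data.frame(
      cell_id = cell$id, parent_id = cell$parent, md_label = cell$md,
      t_birth = t_birth, V_bir = cell$state$v,
      V_bud = if (!is.na(T_unbud)) cell$state$v * exp(mu * T_unbud) else NA_real_,
      V_div = if (divided) sim$state$v else NA_real_,
      T_unbud = T_unbud, T_g1 = T_g1,
      T_bud = if (divided) T_div - T_unbud else NA_real_,
      T_sg2m = if (divided) T_div - T_g1 else NA_real_,
      T_div = T_div, T_whi5 = age(sim$t_whi5),
      T_act_CLN2 = age(sim$t_act[["CLN2"]]),
      T_act_RAD27 = age(sim$t_act[["RAD27"]]),
      T_act_CLB2 = age(sim$t_act[["CLB2"]]),
      arrest = arrest, n_events = sim$n_events,
      stringsAsFactors = FALSE)
    n_done <- n_done + 1L
    if (divided && sim$t_div <= config$t_stop) {
      f <- f_base
      if (config$f_cv > 0) {
        set.seed(.div_seed(config$seed, cell$id))
        repeat {
          f <- stats::rnorm(1, f_base, config$f_cv * f_base)
          if (f > 0.05 && f < 0.95) break
        }
      }
      if (config$partition == "binomial") {
        set.seed(.div_seed(config$seed, cell$id) + 1L)
      }
      prog <- divide_cell(net, sim$state, f, config$partition)
      pending[[length(pending) + 1L]] <-
        list(id = next_id, parent = cell$id, md = "mother",
             state = prog$mother)
      pending[[length(pending) + 1L]] <-
        list(id = next_id + 1L, parent = cell$id, md = "daughter",
             state = prog$daughter)
      next_id <- next_id + 2L
    }
  }
  tab <- do.call(rbind, rows)
  attr(tab, "config") <- config
  attr(tab, "medium") <- net$medium
  if (config$sample_dt > 0) attr(tab, "trajectories") <- trajs
  class(tab) <- c("yc_lineage", "data.frame")
  tab
}

#' Cell-count time series of a culture
#'
#' The number of cells alive at each time: one founder plus one additional
#' cell per completed division. Arrested cells remain alive (but never
#' divide).
#'
#' @param table a `yc_lineage`
#' @param times evaluation grid (default: each division time)
#' @return data.frame with `t` and `n_cells`
#' @export
culture_count_series <- function(table, times = NULL) {
  tdiv <- sort(table$t_birth[!is.na(table$T_div)] +
                 table$T_div[!is.na(table$T_div)])
  if (is.null(times)) times <- c(0, tdiv)
  data.frame(t = times,
             n_cells = 1L + vapply(times, function(t) sum(tdiv <= t), 0L))
}

#' Extant population at an observation time
#'
#' Cells alive at `t_stop`, each followed over its complete
#' birth-to-division cycle: born before `t_stop` and divided after it.
#' Arrested (never-dividing) cells are alive but have no complete cycle
#' record and are not returned.
#'
#' @param table a `yc_lineage`
#' @param t_stop observation time (min)
#' @return subset of the lineage table
#' @export
extant_population <- function(table, t_stop) {
  if (t_stop < min(table$t_birth)) return(table[0, ])
  ok <- !is.na(table$T_div) & table$t_birth < t_stop &
    (table$t_birth + table$T_div) > t_stop
  table[ok, , drop = FALSE]
}

#' Write a lineage table to TSV
#' @param table a `yc_lineage`
#' @param path output file
#' @return the path, invisibly
#' @export
write_lineage_tsv <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Number doubling time of a culture run
#'
#' Estimates the NDT from the culture's count-vs-time series. The series is
#' complete only up to the last processed birth time (divisions of cells
#' still pending when the stop rule hit would be missing after that), so
#' later points are dropped before the regression.
#'
#' @param table a `yc_lineage`
#' @param min_count discard the initial transient below this count
#' @return number doubling time (min)
#' @export
culture_ndt <- function(table, min_count = 4) {
  horizon <- max(table$t_birth)
  tdiv <- sort(table$t_birth[!is.na(table$T_div)] +
                 table$T_div[!is.na(table$T_div)])
  tdiv <- tdiv[tdiv <= horizon]
  counts <- seq_along(tdiv) + 1L
  ndt_estimate(tdiv, counts, min_count = min_count)
}
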