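# Default parameter set for the wild-type network.
#
# All rate constants are in concentration-based units: min^-1 for first-order
# steps, nM^-1 min^-1 for bimolecular steps, mRNA min^-1 per active gene copy
# for transcription, protein mRNA^-1 min^-1 (at the reference volume) for
# translation. The engines convert them to molecule-number propensities with
# the 1.67 nM.fL conversion constant.
#
# There is no machine-readable reference parameter table for this network;
# the values below are this package's own calibration of the published
# mechanism, chosen so that the deterministic model runs a stable
# limit cycle with period = mass doubling time, with the published event
# ordering (Start, budding, DNA-synthesis onset, mitosis, exit, division),
# mRNA means of a few copies per cell, protein levels of hundreds to
# thousands of molecules, and the stated mRNA half-lives (5-10 min; 3 min
# for CLN1, CLN2, CLB5). See the methods vignette for the calibration
# rationale of each group.

#' Default parameter set of the wild-type cell-cycle network
#'
#' Returns the named list of rate constants, thresholds and structural
#' constants consumed by [build_wildtype()]. Group prefixes: `ktm_` mRNA
#' synthesis per active gene copy, `kdm_` mRNA decay, `ktl_` translation,
#' `kdp_` basal protein decay, `kon_`/`koff_` promoter (in)activation,
#' `kp_x_y` phosphorylation of x by kinase y, `kq_x_y` dephosphorylation of
#' x by phosphatase y, `ka_`/`kdi_` complex association/dissociation,
#' `kd20_` Cdc20:APC-mediated degradation, `kdh_` Cdh1:APC-mediated
#' degradation, `th_` event thresholds (nM), `eff_` indicator efficiencies.
#'
#' @param ... named overrides of individual defaults
#' @return a named list of class `yc_params`
#' @export
default_params <- function(...) {
  p <- list(
    # -- conversion / reference volume -----------------------------------
    conv = 1.67,          # nM.fL per molecule
    v_ref = 45,           # fL; volume at which concentration rates were set
    # -- APC phosphorylation ladder --------------------------------------
    beta_apc = 0.525,     # Cdc20 affinity decreases by beta^(n-k)
    n_apc = 11L,

    # -- regulated genes (mRNA half-lives: 3 min for CLN1/CLN2/CLB5, ----
    #    5-10 min otherwise)
    ktm_CLN1 = 3.0,  kdm_CLN1 = log(2) / 3, ktl_CLN1 = 70, kdp_CLN1 = 0.20,
    ktm_CLN2 = 3.0,  kdm_CLN2 = log(2) / 3, ktl_CLN2 = 70, kdp_CLN2 = 0.20,
    ktm_CLB5 = 1.6,  kdm_CLB5 = log(2) / 3, ktl_CLB5 = 15, kdp_CLB5 = 0.03,
    ktm_CLB2 = 0.95,  kdm_CLB2 = 0.10,       ktl_CLB2 = 50, kdp_CLB2 = 0.01,
    ktm_SIC1 = 1.4,  kdm_SIC1 = 0.10,       ktl_SIC1 = 20, kdp_SIC1 = 0.01,
    ktm_SWI5 = 1.0,  kdm_SWI5 = 0.10,       ktl_SWI5 = 8,  kdp_SWI5 = 0.03,
    ktm_CDC20 = 1.5, kdm_CDC20 = 0.10,      ktl_CDC20 = 10, kdp_CDC20 = 0.05,
    # promoter activation (per nM of transcription factor) / inactivation
    kon_CLN1 = 0.08,  koff_CLN1 = 2.4,
    kon_CLN2 = 0.08,  koff_CLN2 = 2.4,
    kon_CLB5 = 0.08,  koff_CLB5 = 2.4,
    kon_CLB2 = 0.09,  koff_CLB2 = 2.4,
    kon_SIC1 = 0.09,  koff_SIC1 = 2.4,
    kon_SWI5 = 0.06,  koff_SWI5 = 2.4,
    kon_CDC20 = 0.03, koff_CDC20 = 2.4,

    # -- constitutive genes ----------------------------------------------
    ktm_CLN3 = 0.6,  kdm_CLN3 = 0.10, ktl_CLN3 = 6.7,  kdp_CLN3 = 0.05,
    ktm_WHI5 = 0.6,  kdm_WHI5 = 0.10, ktl_WHI5 = 16,   kdp_WHI5 = 0.005,
    ktm_SBF  = 0.6,  kdm_SBF  = 0.10, ktl_SBF  = 5.4,  kdp_SBF  = 0.005,
    ktm_FKH2 = 0.6,  kdm_FKH2 = 0.10, ktl_FKH2 = 5.4,  kdp_FKH2 = 0.005,
    ktm_APC  = 0.6,  kdm_APC  = 0.10, ktl_APC  = 5.4,  kdp_APC  = 0.005,
    ktm_NET1 = 0.6,  kdm_NET1 = 0.10, ktl_NET1 = 16,   kdp_NET1 = 0.005,
    ktm_CDH1 = 0.6,  kdm_CDH1 = 0.10, ktl_CDH1 = 5.4,  kdp_CDH1 = 0.005,
    ktm_CDC14 = 0.6, kdm_CDC14 = 0.10, ktl_CDC14 = 10.8, kdp_CDC14 = 0.005,
    ktm_HBF  = 0.6,  kdm_HBF  = 0.10, ktl_HBF  = 5.4,  kdp_HBF  = 0.005,
    ktm_HT1  = 1.0,  kdm_HT1  = 0.10, ktl_HT1  = 10,   kdp_HT1  = 0.03,

    # -- multisite phosphorylation: kinase rate constants ----------------
    # Whi5 (n=10, m=2, ordered): the Cln1,2 positive feedback loop
    kp_whi5_cln3 = 0.015, kp_whi5_cln1 = 0.016, kp_whi5_cln2 = 0.016,
    kq_whi5_hbf = 0.0036, kq_whi5_cdc14 = 0.010,
    # SBF (n=4, m=0, ordered): inactivated by Clb2
    kp_sbf_clb2 = 0.040,
    kq_sbf_hbf = 0.003, kq_sbf_cdc14 = 0.002,
    # Sic1 (n=9, m=5, disordered): the Clb5,6 double-negative loop
    kp_sic1_cln1 = 0.003, kp_sic1_cln2 = 0.003, kp_sic1_cln3 = 0.0015,
    kp_sic1_clb5 = 0.014, kp_sic1_clb2 = 0.004,
    kq_sic1_hbf = 0.0033, kq_sic1_cdc14 = 0.020,
    # Cdh1 (n=11, m=0, ordered)
    kp_cdh1_cln1 = 0.003, kp_cdh1_cln2 = 0.003, kp_cdh1_cln3 = 0.002,
    kp_cdh1_clb5 = 0.006, kp_cdh1_clb2 = 0.008,
    kq_cdh1_hbf = 0.002, kq_cdh1_cdc14 = 0.020,
    # Net1 (n=8, m=3, ordered): releases Cdc14 when phosphorylated
    kp_net1_clb2 = 0.005,
    kq_net1_ht1 = 0.004, kq_net1_hbf = 0.0005,
    # Swi5 (n=3, m=0, ordered)
    kp_swi5_clb2 = 0.005,
    kq_swi5_cdc14 = 0.020, kq_swi5_hbf = 0.001,
    # Fkh2 (n=2, activated when both sites phosphorylated):
    # the Clb2 positive feedback loop
    kp_fkh2_cln1 = 0.0005, kp_fkh2_cln2 = 0.0005, kp_fkh2_cln3 = 0.0005,
    kp_fkh2_clb5 = 0.002, kp_fkh2_clb2 = 0.008,
    kq_fkh2_hbf = 0.003, kq_fkh2_cdc14 = 0.008,
    # APC (n=11, ordered; activity through the Cdc20 affinity ladder)
    kp_apc_clb2 = 0.004,
    kq_apc_hbf = 0.004, kq_apc_cdc14 = 0.002,

    # -- complexes --------------------------------------------------------
    ka_whi5_sbf = 0.50,  kdi_whi5_sbf = 0.05,
    ka_clb5_sic1 = 0.05, kdi_clb5_sic1 = 0.05,
    ka_clb2_sic1 = 0.05, kdi_clb2_sic1 = 0.10,
    ka_net1_cdc14 = 0.05, kdi_net1_cdc14 = 0.05,
    ka_cdc20_apc = 0.05, kdi_cdc20_apc = 0.20,

    # -- regulated degradation routes ------------------------------------
    kd20_clb2 = 0.010,   # Clb2 by Cdc20:APC (destruction-box route)
    kd20_clb5 = 0.010,   # Clb5 by Cdc20:APC
    kd20_ht1 = 0.050,    # Ht1 by Cdc20:APC
    kdh_clb2 = 0.020,    # Clb2 by Cdh1:APC
    kdh_cdc20 = 0.010,   # Cdc20 by Cdh1:APC
    kd_sic1_p = 1.0,     # SCF route: Sic1 with >= 6 phosphates

    # -- G1/S reporter promoter (RAD27) ----------------------------------
    kon_RAD27 = 0.015, koff_RAD27 = 2.4,
    w_rad27_cln1 = 1.0, w_rad27_cln2 = 1.0,
    w_rad27_cln3 = 0.3, w_rad27_clb5 = 0.6,

    # -- indicator functions ---------------------------------------------
    ks_bud = 0.14, kd_bud = 0.25,
    eff_bud_cln1 = 1.0, eff_bud_cln2 = 1.0, eff_bud_cln3 = 0.2,
    eff_bud_clb5 = 0.5, eff_bud_clb2 = 0.1,
    ks_dna = 0.45, kd_dna = 0.25,
    eff_dna_clb5 = 1.0, eff_dna_clb2 = 0.5,

    # -- event thresholds (nM unless stated) -----------------------------
    th_div = 12.5,       # division: [Clb2] falls below this (when armed)
    th_arm = 25,         # arming level for the division detector
    th_bud = 25,         # budding: bud_ss rises through this
    th_dna = 30,         # DNA-synthesis onset: dna_ss rises through this
    th_whi5 = 200,       # Whi5 nuclear exit: nuclear [Whi5] falls below
    th_act_cln2 = 0.15,  # gene-activity thresholds (dimensionless)
    th_act_clb2 = 0.20,
    th_act_rad27 = 0.20,
    arrest_window = 500  # min without the next milestone => arrested
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(over)] <- over
  }
  validate_params(p)
  structure(p, class = "yc_params")
}

#' Validate a parameter set
#'
#' Checks that all rate constants are non-negative, 0 < beta_apc < 1, and
#' all thresholds positive.
#'
#' @param p parameter list as returned by [default_params()]
#' @return the parameter list, invisibly
#' @export
validate_params <- function(p) {
  rate_names <- grep("^(ktm|kdm|ktl|kdp|kon|koff|kp|kq|ka|kdi|kd20|kdh|kd|ks|w)_",
                     names(p), value = TRUE)
  vals <- unlist(p[rate_names])
  if (any(vals < 0)) {
    stop("negative rate constant(s): ",
         paste(rate_names[vals < 0], collapse = ", "))
  }
  if (p$beta_apc <= 0 || p$beta_apc >= 1) stop("beta_apc must lie in (0, 1)")
  th <- unlist(p[grep("^th_", names(p))])
  if (any(th <= 0)) stop("all thresholds must be positive")
  if (p$arrest_window <= 0) stop("arrest_window must be positive")
  invisible(p)
}
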