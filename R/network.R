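# Construction of the full wild-type reaction network.
#
# 17 genes. Seven (CLN1, CLN2, CLB5, CLB2, SIC1, SWI5, CDC20) are
# transcribed from discrete two-state promoters driven by their
# transcription factors (SBF for the G1/S cyclins; Fkh2 for the mitotic
# regulon; Swi5 for SIC1); the other ten (CLN3, WHI5, SBF, FKH2, APC, NET1,
# CDH1, CDC14, HBF, HT1) are constitutive. "Clb5" stands for Clb5+Clb6,
# "Clb2" for Clb1+Clb2, and "Sic1" is the composite of Sic1 and the
# inhibitory domain of Cdc6. RAD27 is carried as a promoter-activity
# reporter of the G1/S regulon (no mRNA/protein species). Cdc28 is not a
# variable: each cyclin count doubles as the count of its CDK heterodimer.

.regulated_genes <- c("CLN1", "CLN2", "CLB5", "CLB2", "SIC1", "SWI5", "CDC20")
.constitutive_genes <- c("CLN3", "WHI5", "SBF", "FKH2", "APC", "NET1",
                         "CDH1", "CDC14", "HBF", "HT1")
.all_genes <- c(.regulated_genes, .constitutive_genes)

# protein stem for each gene and which species its translation produces
.gene_protein <- c(
  CLN1 = "Cln1", CLN2 = "Cln2", CLB5 = "Clb5", CLB2 = "Clb2",
  SIC1 = "Sic1_P0", SWI5 = "Swi5_P0", CDC20 = "Cdc20", CLN3 = "Cln3",
  WHI5 = "Whi5_P0", SBF = "SBF_P0", FKH2 = "Fkh2_P0", APC = "APC_P0",
  NET1 = "Net1_P0", CDH1 = "Cdh1_P0", CDC14 = "Cdc14", HBF = "Hbf",
  HT1 = "Ht1"
)

#' Phosphorylation-chain definitions of the wild-type network
#'
#' Returns the eight [phospho_chain()] definitions with the published site
#' counts and activity rules: Whi5 (n=10, m=2), SBF (n=4, m=0), Sic1 (n=9,
#' m=5, disordered), Cdh1 (n=11, m=0), Net1 (n=8, m=3), Swi5 (n=3, m=0),
#' Fkh2 (n=2, active only fully phosphorylated) and APC (n=11, whose
#' activity is expressed through the Cdc20 affinity ladder rather than a
#' mask).
#'
#' @param p parameter set
#' @return named list of `yc_phospho_def`
#' @export
wildtype_chains <- function(p = default_params()) {
  list(
    Whi5 = phospho_chain("Whi5", 10L, m = 2L, order_mode = "ordered",
      kinases = c(Cln3 = p$kp_whi5_cln3, Cln1 = p$kp_whi5_cln1,
                  Cln2 = p$kp_whi5_cln2),
      phosphatases = c(Hbf = p$kq_whi5_hbf, Cdc14 = p$kq_whi5_cdc14)),
    SBF = phospho_chain("SBF", 4L, m = 0L, order_mode = "ordered",
      kinases = c(Clb2 = p$kp_sbf_clb2),
      phosphatases = c(Hbf = p$kq_sbf_hbf, Cdc14 = p$kq_sbf_cdc14)),
    Sic1 = phospho_chain("Sic1", 9L, m = 5L, order_mode = "disordered",
      kinases = c(Cln1 = p$kp_sic1_cln1, Cln2 = p$kp_sic1_cln2,
                  Cln3 = p$kp_sic1_cln3, Clb5 = p$kp_sic1_clb5,
                  Clb2 = p$kp_sic1_clb2),
      phosphatases = c(Hbf = p$kq_sic1_hbf, Cdc14 = p$kq_sic1_cdc14)),
    Cdh1 = phospho_chain("Cdh1", 11L, m = 0L, order_mode = "ordered",
      kinases = c(Cln1 = p$kp_cdh1_cln1, Cln2 = p$kp_cdh1_cln2,
                  Cln3 = p$kp_cdh1_cln3, Clb5 = p$kp_cdh1_clb5,
                  Clb2 = p$kp_cdh1_clb2),
      phosphatases = c(Hbf = p$kq_cdh1_hbf, Cdc14 = p$kq_cdh1_cdc14)),
    Net1 = phospho_chain("Net1", 8L, m = 3L, order_mode = "ordered",
      kinases = c(Clb2 = p$kp_net1_clb2),
      phosphatases = c(Ht1 = p$kq_net1_ht1, Hbf = p$kq_net1_hbf)),
    Swi5 = phospho_chain("Swi5", 3L, m = 0L, order_mode = "ordered",
      kinases = c(Clb2 = p$kp_swi5_clb2),
      phosphatases = c(Cdc14 = p$kq_swi5_cdc14, Hbf = p$kq_swi5_hbf)),
    Fkh2 = phospho_chain("Fkh2", 2L, active_rule = "eq_n",
      order_mode = "ordered",
      kinases = c(Cln1 = p$kp_fkh2_cln1, Cln2 = p$kp_fkh2_cln2,
                  Cln3 = p$kp_fkh2_cln3, Clb5 = p$kp_fkh2_clb5,
                  Clb2 = p$kp_fkh2_clb2),
      phosphatases = c(Hbf = p$kq_fkh2_hbf, Cdc14 = p$kq_fkh2_cdc14)),
    APC = phospho_chain("APC", 11L, m = 0L, order_mode = "ordered",
      kinases = c(Clb2 = p$kp_apc_clb2),
      phosphatases = c(Hbf = p$kq_apc_hbf, Cdc14 = p$kq_apc_cdc14))
  )
}

#' Build the wild-type reaction network
#'
#' Assembles species and elementary reactions for one strain in one medium:
#' gene expression (two-state regulated promoters, constitutive synthesis,
#' mRNA decay, volume-scaled translation with the CLN3 V^2 exception),
#' the eight multisite phosphorylation chains (including phosphorylation of
#' complex-bound Whi5, Sic1 and Net1, with release of the partner when the
#' bound protein crosses its activity boundary), the stoichiometric
#' complexes Whi5:SBF, Clb5:Sic1, Clb2:Sic1 and Net1:Cdc14 (RENT), the
#' Cdc20:APC affinity ladder, and the regulated degradation routes
#' (Cdc20:APC against Clb2/Clb5/Ht1; Cdh1:APC against Clb2/Cdc20; the SCF
#' route against Sic1 with >= 6 phosphates).
#'
#' @param params parameter set from [default_params()]
#' @param medium a [medium_growth()] object
#' @param genotype list of structural edits, normally produced by
#'   [apply_mutant()]: `overexpress` (named numeric, gene -> constitutive
#'   transcription rate), `clb2_db_delta` (drop the Cdc20:APC route against
#'   Clb2)
#' @return object of class `yc_network`
#' @export
build_wildtype <- function(params = default_params(),
                           medium = medium_growth("glucose"),
                           genotype = list()) {
  p <- validate_params(params)
  need <- setdiff(names(default_params()), names(p))
  if (length(need)) stop("missing parameter: ", paste(need, collapse = ", "))
  geno <- utils::modifyList(
    list(overexpress = numeric(), clb2_db_delta = FALSE), genotype)

  chains <- wildtype_chains(p)
  buf <- new_rxn_buffer()
  species <- character()
  roles <- character()
  add_species <- function(nm, role) {
    species <<- c(species, nm)
    roles <<- c(roles, rep(role, length(nm)))
  }

  # ---- species ---------------------------------------------------------
  add_species(paste0("mRNA_", .all_genes), "mrna")
  for (g in c(.regulated_genes, "RAD27")) {
    add_species(paste0("G_", g, c("_off", "_on")), "promoter")
  }
  add_species(c("Cln1", "Cln2", "Cln3", "Clb5", "Clb2", "Cdc20", "Cdc14",
                "Ht1", "Hbf"), "protein")
  for (ch in chains) add_species(phospho_species(ch), "protein")
  whi5_bound <- paste0("Whi5P", 0:2, "_SBF")
  clb5_sic1 <- paste0("Clb5_Sic1P", 0:5)
  clb2_sic1 <- paste0("Clb2_Sic1P", 0:5)
  rent <- paste0("RENT", 0:3)
  c20apc <- paste0("C20APC", 0:11)
  add_species(c(whi5_bound, clb5_sic1, clb2_sic1, rent, c20apc), "complex")

  # ---- gene expression -------------------------------------------------
  tf_of <- c(CLN1 = "SBF_P0", CLN2 = "SBF_P0", CLB5 = "SBF_P0",
             CLB2 = "Fkh2_P2", CDC20 = "Fkh2_P2", SWI5 = "Fkh2_P2",
             SIC1 = "Swi5_P0")
  for (g in .regulated_genes) {
    gon <- paste0("G_", g, "_on"); goff <- paste0("G_", g, "_off")
    ktm <- p[[paste0("ktm_", g)]]
    if (g == "CLB2") ktm <- ktm * medium$clb2_factor
    push_rxn(buf, reaction(c(goff, tf_of[[g]]), c(gon, tf_of[[g]]),
                           p[[paste0("kon_", g)]], "bimolecular",
                           group = paste0("promoter:", g)))
    push_rxn(buf, reaction(gon, goff, p[[paste0("koff_", g)]],
                           "unimolecular", group = paste0("promoter:", g)))
    if (ktm > 0) {
      push_rxn(buf, reaction(gon, c(gon, paste0("mRNA_", g)), ktm,
                             "unimolecular", group = paste0("transcription:", g)))
    }
  }
  for (g in .constitutive_genes) {
    ktm <- p[[paste0("ktm_", g)]]
    if (ktm > 0) {
      push_rxn(buf, reaction(character(), paste0("mRNA_", g), ktm,
                             "zero_order", group = paste0("transcription:", g)))
    }
  }
  for (g in names(geno$overexpress)) {
    if (!g %in% .all_genes) stop("overexpression of unknown gene ", g)
    push_rxn(buf, reaction(character(), paste0("mRNA_", g),
                           geno$overexpress[[g]], "zero_order",
                           group = paste0("transcription:", g, ":overexpress")))
  }
  # G1/S regulon reporter promoter: activated by Cln1,2,3 and Clb5 with
  # gene-specific efficiencies
  rad_w <- c(Cln1 = p$w_rad27_cln1, Cln2 = p$w_rad27_cln2,
             Cln3 = p$w_rad27_cln3, Clb5 = p$w_rad27_clb5)
  for (cyc in names(rad_w)) {
    push_rxn(buf, reaction(c("G_RAD27_off", cyc), c("G_RAD27_on", cyc),
                           p$kon_RAD27 * rad_w[[cyc]], "bimolecular",
                           group = "promoter:RAD27"))
  }
  push_rxn(buf, reaction("G_RAD27_on", "G_RAD27_off", p$koff_RAD27,
                         "unimolecular", group = "promoter:RAD27"))

  for (g in .all_genes) {
    m <- paste0("mRNA_", g)
    push_rxn(buf, reaction(m, character(), p[[paste0("kdm_", g)]],
                           "unimolecular", group = paste0("mrna_decay:", g)))
    scal <- if (g == "CLN3") "cln3_translation" else "translation"
    push_rxn(buf, reaction(m, c(m, .gene_protein[[g]]),
                           p[[paste0("ktl_", g)]], scal,
                           group = paste0("translation:", g)))
  }

  # ---- basal protein turnover (free forms) -----------------------------
  basal <- list(
    CLN1 = "Cln1", CLN2 = "Cln2", CLN3 = "Cln3", CLB5 = "Clb5",
    CLB2 = "Clb2", CDC20 = "Cdc20", CDC14 = "Cdc14", HT1 = "Ht1",
    HBF = "Hbf",
    WHI5 = phospho_species(chains$Whi5), SBF = phospho_species(chains$SBF),
    SIC1 = phospho_species(chains$Sic1), CDH1 = phospho_species(chains$Cdh1),
    NET1 = phospho_species(chains$Net1), SWI5 = phospho_species(chains$Swi5),
    FKH2 = phospho_species(chains$Fkh2), APC = phospho_species(chains$APC)
  )
  for (g in names(basal)) {
    kd <- p[[paste0("kdp_", g)]]
    if (kd > 0) for (sp in basal[[g]]) {
      push_rxn(buf, reaction(sp, character(), kd, "unimolecular",
                             group = paste0("protein_decay:", g)))
    }
  }

  # ---- free-form phosphorylation chains --------------------------------
  for (ch in chains) for (r in expand_phospho_chain(ch)$reactions) {
    push_rxn(buf, r)
  }

  # ---- Whi5:SBF (only active, <=2-phosphate Whi5 binds free active SBF)
  for (k in 0:2) {
    w <- paste0("Whi5_P", k); cx <- paste0("Whi5P", k, "_SBF")
    push_rxn(buf, reaction(c(w, "SBF_P0"), cx, p$ka_whi5_sbf, "bimolecular",
                           group = "complex:Whi5_SBF"))
    push_rxn(buf, reaction(cx, c(w, "SBF_P0"), p$kdi_whi5_sbf, "unimolecular",
                           group = "complex:Whi5_SBF"))
  }
  # phosphorylation of SBF-bound Whi5; crossing m = 2 releases SBF
  wkin <- chains$Whi5$kinases
  wph <- chains$Whi5$phosphatases
  for (kin in names(wkin)) for (k in 0:2) {
    from <- paste0("Whi5P", k, "_SBF")
    prod <- if (k < 2) c(paste0("Whi5P", k + 1, "_SBF"), kin)
            else c("Whi5_P3", "SBF_P0", kin)
    push_rxn(buf, reaction(c(from, kin), prod, wkin[[kin]], "bimolecular",
                           group = "phospho:Whi5_bound"))
  }
  for (ph in names(wph)) for (k in 1:2) {
    push_rxn(buf, reaction(c(paste0("Whi5P", k, "_SBF"), ph),
                           c(paste0("Whi5P", k - 1, "_SBF"), ph),
                           wph[[ph]], "bimolecular",
                           group = "phospho:Whi5_bound"))
  }

  # ---- Clb:Sic1 complexes (Sic1 with <= 5 phosphates binds either Clb)
  skin <- chains$Sic1$kinases
  sph <- chains$Sic1$phosphatases
  n_sic <- chains$Sic1$n_sites
  for (cyc in c("Clb5", "Clb2")) {
    ka <- if (cyc == "Clb5") p$ka_clb5_sic1 else p$ka_clb2_sic1
    kd <- if (cyc == "Clb5") p$kdi_clb5_sic1 else p$kdi_clb2_sic1
    for (k in 0:5) {
      s <- paste0("Sic1_P", k); cx <- paste0(cyc, "_Sic1P", k)
      push_rxn(buf, reaction(c(cyc, s), cx, ka, "bimolecular",
                             group = paste0("complex:", cyc, "_Sic1")))
      push_rxn(buf, reaction(cx, c(cyc, s), kd, "unimolecular",
                             group = paste0("complex:", cyc, "_Sic1")))
    }
    # disordered phosphorylation of bound Sic1; crossing m = 5 releases Clb
    for (kin in names(skin)) for (k in 0:5) {
      from <- paste0(cyc, "_Sic1P", k)
      prod <- if (k < 5) c(paste0(cyc, "_Sic1P", k + 1), kin)
              else c(cyc, "Sic1_P6", kin)
      push_rxn(buf, reaction(c(from, kin), prod, skin[[kin]], "bimolecular",
                             mult = n_sic - k, group = "phospho:Sic1_bound"))
    }
    for (ph in names(sph)) for (k in 1:5) {
      push_rxn(buf, reaction(c(paste0(cyc, "_Sic1P", k), ph),
                             c(paste0(cyc, "_Sic1P", k - 1), ph),
                             sph[[ph]], "bimolecular", mult = k,
                             group = "phospho:Sic1_bound"))
    }
  }

  # ---- RENT = Net1:Cdc14 (Net1 with <= 3 phosphates binds Cdc14) -------
  for (k in 0:3) {
    nsp <- paste0("Net1_P", k); cx <- paste0("RENT", k)
    push_rxn(buf, reaction(c(nsp, "Cdc14"), cx, p$ka_net1_cdc14,
                           "bimolecular", group = "complex:RENT"))
    push_rxn(buf, reaction(cx, c(nsp, "Cdc14"), p$kdi_net1_cdc14,
                           "unimolecular", group = "complex:RENT"))
  }
  for (k in 0:3) {
    from <- paste0("RENT", k)
    prod <- if (k < 3) c(paste0("RENT", k + 1), "Clb2")
            else c("Net1_P4", "Cdc14", "Clb2")
    push_rxn(buf, reaction(c(from, "Clb2"), prod, p$kp_net1_clb2,
                           "bimolecular", group = "phospho:Net1_bound"))
  }
  for (ph in names(chains$Net1$phosphatases)) for (k in 1:3) {
    push_rxn(buf, reaction(c(paste0("RENT", k), ph),
                           c(paste0("RENT", k - 1), ph),
                           chains$Net1$phosphatases[[ph]], "bimolecular",
                           group = "phospho:Net1_bound"))
  }

  # ---- Cdc20:APC ladder ------------------------------------------------
  for (k in 0:11) {
    apck <- paste0("APC_P", k); cx <- paste0("C20APC", k)
    push_rxn(buf, reaction(c("Cdc20", apck), cx,
                           p$ka_cdc20_apc * apc_affinity_factor(k, p),
                           "bimolecular", group = "complex:C20APC"))
    push_rxn(buf, reaction(cx, c("Cdc20", apck), p$kdi_cdc20_apc,
                           "unimolecular", group = "complex:C20APC"))
  }

  # ---- regulated degradation -------------------------------------------
  for (k in 0:11) {
    cx <- paste0("C20APC", k)
    if (!geno$clb2_db_delta && p$kd20_clb2 > 0) {
      push_rxn(buf, reaction(c("Clb2", cx), cx, p$kd20_clb2, "bimolecular",
                             group = "degradation:Clb2_by_Cdc20APC"))
    }
    if (p$kd20_clb5 > 0) {
      push_rxn(buf, reaction(c("Clb5", cx), cx, p$kd20_clb5, "bimolecular",
                             group = "degradation:Clb5_by_Cdc20APC"))
    }
    if (p$kd20_ht1 > 0) {
      push_rxn(buf, reaction(c("Ht1", cx), cx, p$kd20_ht1, "bimolecular",
                             group = "degradation:Ht1_by_Cdc20APC"))
    }
  }
  if (p$kdh_clb2 > 0) {
    push_rxn(buf, reaction(c("Clb2", "Cdh1_P0"), "Cdh1_P0", p$kdh_clb2,
                           "bimolecular", group = "degradation:Clb2_by_Cdh1APC"))
  }
  if (p$kdh_cdc20 > 0) {
    push_rxn(buf, reaction(c("Cdc20", "Cdh1_P0"), "Cdh1_P0", p$kdh_cdc20,
                           "bimolecular", group = "degradation:Cdc20_by_Cdh1APC"))
  }
  if (p$kd_sic1_p > 0) for (k in 6:9) {
    push_rxn(buf, reaction(paste0("Sic1_P", k), character(), p$kd_sic1_p,
                           "unimolecular", group = "degradation:Sic1_SCF"))
  }

  net <- structure(list(
    species = data.frame(name = species, role = roles,
                         stringsAsFactors = FALSE),
    reactions = rxn_list(buf),
    params = p, medium = medium, genotype = geno,
    chains = chains,
    index = .wildtype_index(p, chains)
  ), class = "yc_network")
  net$init <- initial_state(net)
  validate_network(net)
  net
}

# species groups the engines and scoring functions need
.wildtype_index <- function(p, chains) {
  totals <- list(
    Cln1 = "Cln1", Cln2 = "Cln2", Cln3 = "Cln3",
    Clb5 = c("Clb5", paste0("Clb5_Sic1P", 0:5)),
    Clb2 = c("Clb2", paste0("Clb2_Sic1P", 0:5)),
    Cdc20 = c("Cdc20", paste0("C20APC", 0:11)),
    Cdc14 = c("Cdc14", paste0("RENT", 0:3)),
    Ht1 = "Ht1", Hbf = "Hbf",
    Whi5 = c(phospho_species(chains$Whi5), paste0("Whi5P", 0:2, "_SBF")),
    SBF = c(phospho_species(chains$SBF), paste0("Whi5P", 0:2, "_SBF")),
    Sic1 = c(phospho_species(chains$Sic1), paste0("Clb5_Sic1P", 0:5),
             paste0("Clb2_Sic1P", 0:5)),
    Cdh1 = phospho_species(chains$Cdh1),
    Net1 = c(phospho_species(chains$Net1), paste0("RENT", 0:3)),
    Swi5 = phospho_species(chains$Swi5),
    Fkh2 = phospho_species(chains$Fkh2),
    APC = c(phospho_species(chains$APC), paste0("C20APC", 0:11))
  )
  list(
    totals = totals,
    clb2_free = "Clb2",
    whi5_nuclear = c(paste0("Whi5_P", 0:2), paste0("Whi5P", 0:2, "_SBF")),
    bud_weights = c(Cln1 = p$eff_bud_cln1, Cln2 = p$eff_bud_cln2,
                    Cln3 = p$eff_bud_cln3, Clb5 = p$eff_bud_clb5,
                    Clb2 = p$eff_bud_clb2),
    dna_weights = c(Clb5 = p$eff_dna_clb5, Clb2 = p$eff_dna_clb2),
    act_promoters = c(CLN2 = "G_CLN2_on", RAD27 = "G_RAD27_on",
                      CLB2 = "G_CLB2_on")
  )
}

#' Default initial state of a network
#'
#' A newborn G1 daughter cell of 30 fL: Whi5 bound to all SBF plus a free
#' nuclear excess, abundant unphosphorylated Sic1 and active Cdh1, Cdc14
#' sequestered in RENT, constitutive mRNAs at their stationary means,
#' regulated promoters off, cyclins (except a basal Cln3 pool) absent.
#' Simulations are routinely run in from this state for a few cycles before
#' statistics are collected.
#'
#' @param net a `yc_network`
#' @param v0 initial volume (fL)
#' @return named integer vector of molecule counts over `net$species$name`
#' @export
initial_state <- function(net, v0 = 30) {
  sp <- net$species$name
  x <- stats::setNames(numeric(length(sp)), sp)
  p <- net$params
  cc <- function(conc) round(conc * v0 / p$conv)  # nM -> molecules at v0
  for (g in .constitutive_genes) {
    x[paste0("mRNA_", g)] <- round(p[[paste0("ktm_", g)]] / p[[paste0("kdm_", g)]])
  }
  for (g in c(.regulated_genes, "RAD27")) x[paste0("G_", g, "_off")] <- 1
  x["Whi5P0_SBF"] <- cc(100)     # all SBF inhibited
  x["Whi5_P0"] <- cc(200)        # free nuclear Whi5 excess
  x["Sic1_P0"] <- cc(200)
  x["Cdh1_P0"] <- cc(100)
  x["RENT0"] <- cc(200)          # all Cdc14 sequestered
  x["Net1_P0"] <- cc(100)        # free Net1 beyond the RENT pool
  x["Fkh2_P0"] <- cc(100)
  x["Swi5_P0"] <- cc(100)
  x["APC_P0"] <- cc(100)
  x["Hbf"] <- cc(100)
  x["Ht1"] <- cc(100)
  x["Cln3"] <- cc(20)
  x
}

#' Validate a network's internal consistency
#'
#' Checks that every reaction references declared species, no reaction has
#' more than two reactant molecules, and each promoter's two states sum to
#' the gene copy number (1) in the initial state.
#'
#' @param net a `yc_network`
#' @return the network, invisibly
#' @export
validate_network <- function(net) {
  sp <- net$species$name
  if (anyDuplicated(sp)) stop("duplicated species: ",
                              paste(sp[duplicated(sp)], collapse = ", "))
  for (r in net$reactions) {
    miss <- setdiff(c(r$reactants, r$products), sp)
    if (length(miss)) stop("reaction references undeclared species: ",
                           paste(miss, collapse = ", "))
    if (length(r$reactants) > 2L) stop("reaction with > 2 reactants")
  }
  if (!is.null(net$init)) {
    prom <- grep("^G_.*_(on|off)$", sp, value = TRUE)
    genes <- unique(sub("^G_(.*)_(on|off)$", "\\1", prom))
    for (g in genes) {
      tot <- sum(net$init[paste0("G_", g, c("_on", "_off"))])
      if (tot != 1) stop("promoter states of ", g, " must sum to 1")
    }
  }
  invisible(net)
}

#' @export
print.yc_network <- function(x, ...) {
  cat(sprintf("cell-cycle reaction network: %d species, %d reactions (%s, %s)\n",
              nrow(x$species), length(x$reactions), x$medium$name,
              if (length(x$genotype$overexpress) || x$genotype$clb2_db_delta ||
                  !is.null(x$genotype$label)) {
                x$genotype$label %||% "edited"
              } else "wild type"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
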