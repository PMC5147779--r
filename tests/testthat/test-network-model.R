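# Network construction: media, phospho chains, APC ladder, wild type,
# mutant edits.

test_that("media reproduce the published growth parameters", {
  glu <- medium_growth("glucose")
  expect_equal(glu$mu, 0.007)
  expect_equal(round(glu$mdt), 99)
  expect_equal(glu$f_daughter, 0.40)
  gal <- medium_growth("galactose")
  expect_equal(gal$mu, 0.00467)
  expect_equal(round(gal$mdt), 148)
  expect_equal(gal$f_daughter, 0.36)
  gly <- medium_growth("glycerol-ethanol")
  expect_equal(round(gly$mdt), 174)
  expect_equal(gly$f_daughter, 0.35)
  for (m in list_media()) {
    md <- medium_growth(m)
    expect_equal(md$mdt * md$mu, log(2), tolerance = 1e-12)
    expect_true(md$f_daughter > 0 && md$f_daughter < 0.5)
  }
  expect_error(medium_growth("raffinose"), "known media")
})

test_that("ordered phospho chains expand to n+1 species and 2n reactions per pair", {
  ch <- phospho_chain("X", 1L, m = 0L, kinases = c(K = 1),
                      phosphatases = c(P = 1))
  ex <- expand_phospho_chain(ch)
  expect_length(ex$species, 2)
  expect_length(ex$reactions, 2)

  whi5 <- phospho_chain("Whi5", 10L, m = 2L, kinases = c(K = 0.01),
                        phosphatases = c(P = 0.004))
  ex <- expand_phospho_chain(whi5)
  expect_length(ex$species, 11)
  expect_length(ex$reactions, 20)
  expect_identical(unname(which(ex$active)), 1:3)  # k in {0, 1, 2}

  # activation-type rule: only the fully phosphorylated form is active
  fkh2 <- phospho_chain("Fkh2", 2L, active_rule = "eq_n",
                        kinases = c(K = 1), phosphatases = c(P = 1))
  expect_identical(unname(which(expand_phospho_chain(fkh2)$active)), 3L)

  expect_error(phospho_chain("X", 0L), "n_sites")
  expect_error(phospho_chain("X", 3L, m = 3L), "m < n")
})

test_that("disordered chain multiplicities give the combinatorial rates", {
  ch <- phospho_chain("S", 3L, m = 1L, order_mode = "disordered",
                      kinases = c(K = 1), phosphatases = c(P = 1))
  ex <- expand_phospho_chain(ch)
  tab <- reaction_table(ex$reactions)
  kin <- tab[grepl("\\+ K$", tab$reactants), ]
  expect_equal(kin$mult, c(3, 2, 1))  # n - k free sites
  ph <- tab[grepl("\\+ P$", tab$reactants), ]
  expect_equal(ph$mult, c(1, 2, 3))   # k occupied sites
})

test_that("disordered count-resolved chain matches the site-resolved master equation", {
  # brute-force oracle: 2^n site-resolved CME with symmetric per-site
  # rates; stationary distribution marginalized to the phospho-count
  n <- 2
  kp <- 0.7; kq <- 0.4  # per-site (pseudo-first-order) rates
  states <- expand.grid(s1 = 0:1, s2 = 0:1)
  ns <- nrow(states)
  A <- matrix(0, ns, ns)
  for (i in seq_len(ns)) {
    for (site in 1:n) {
      to <- states[i, ]
      to[site] <- 1 - to[site]
      j <- which(states$s1 == to$s1 & states$s2 == to$s2)
      r <- if (states[i, site] == 0) kp else kq
      A[j, i] <- A[j, i] + r
      A[i, i] <- A[i, i] - r
    }
  }
  A[1, ] <- 1
  p_site <- solve(A, c(1, rep(0, ns - 1)))
  oracle <- tapply(p_site, rowSums(states), sum)  # marginal over count

  # count-resolved chain with the package's multiplicities
  ch <- phospho_chain("S", 2L, m = 0L, order_mode = "disordered",
                      kinases = c(K = 1), phosphatases = c(P = 1))
  tab <- reaction_table(expand_phospho_chain(ch)$reactions)
  # birth-death chain on k = 0..2: up rate kp*(n-k), down rate kq*k
  up <- kp * tab$mult[grepl("\\+ K$", tab$reactants)]
  down <- kq * tab$mult[grepl("\\+ P$", tab$reactants)]
  pi_k <- c(1, up[1] / down[1], up[1] * up[2] / (down[1] * down[2]))
  pi_k <- pi_k / sum(pi_k)
  expect_equal(unname(pi_k), unname(as.vector(oracle)), tolerance = 1e-12)
})

test_that("the APC affinity ladder follows beta^(n-k)", {
  p <- default_params()
  expect_equal(apc_affinity_factor(11, p), 1)
  expect_equal(apc_affinity_factor(10, p), 0.525)
  expect_equal(apc_affinity_factor(0, p), 0.525^11)
  expect_error(apc_affinity_factor(12, p), "0..11")
  expect_error(apc_affinity_factor(-1, p), "0..11")
})

test_that("wild-type network has the full gene complement and valid reactions", {
  net <- strain_network()
  sp <- net$species
  expect_length(grep("^mRNA_", sp$name), 17)            # 17 genes
  expect_length(names(net$index$totals), 17)            # 17 proteins
  regulated <- c("CLN1", "CLN2", "CLB5", "CLB2", "SIC1", "SWI5", "CDC20")
  for (g in c(regulated, "RAD27")) {
    expect_true(all(paste0("G_", g, c("_on", "_off")) %in% sp$name))
  }
  # every reaction: <= 2 reactant molecules, all species declared
  for (r in net$reactions) {
    expect_lte(length(r$reactants), 2)
    expect_true(all(c(r$reactants, r$products) %in% sp$name))
  }
  expect_gt(length(net$reactions), 400)  # elementary-reaction expansion
  expect_silent(validate_network(net))
})

test_that("phospho reactions conserve each chain's total protein", {
  net <- strain_network()
  cnet <- compile_network(net)
  tab <- reaction_table(net)
  phospho <- grepl("^phospho:", tab$group)
  for (prot in c("Whi5", "Sic1", "Cdh1", "Net1", "Swi5", "Fkh2", "APC")) {
    members <- net$index$totals[[prot]]
    drift <- rowSums(cnet$S[phospho, members, drop = FALSE])
    expect_true(all(drift == 0),
                label = paste("conservation of", prot, "under (de)phosphorylation"))
  }
})

test_that("mutant edits behave as declared", {
  net <- strain_network()
  cat0 <- mutant_catalog()

  dd <- apply_mutant(net, cat0$cln1d_cln2d)
  tab <- reaction_table(dd)
  expect_false(any(tab$group %in% c("transcription:CLN1", "transcription:CLN2")))
  expect_true(any(tab$group == "transcription:CLN3"))

  # identity scale edit leaves the network unchanged
  ident <- apply_mutant(net, mutant_spec("id", list(edit_scale("kp_whi5_cln1", 1))))
  expect_equal(reaction_table(ident)[1:4], reaction_table(net)[1:4])

  # stable Clb2: strictly fewer reactions, basal route retained
  dbd <- apply_mutant(net, cat0$clb2_dbd)
  expect_lt(length(dbd$reactions), length(net$reactions))
  tb <- reaction_table(dbd)
  expect_false(any(grepl("degradation:Clb2_by", tb$group)))
  expect_true(any(tb$group == "protein_decay:CLB2"))

  # deletion is idempotent
  d1 <- apply_mutant(net, cat0$sic1d)
  d2 <- apply_mutant(d1, cat0$sic1d)
  expect_equal(reaction_table(d1), reaction_table(d2))

  # disjoint edits commute
  ab <- apply_mutant(apply_mutant(net, cat0$cln1d), cat0$swi5d)
  ba <- apply_mutant(apply_mutant(net, cat0$swi5d), cat0$cln1d)
  expect_equal(reaction_table(ab), reaction_table(ba))

  expect_error(apply_mutant(net, mutant_spec("x", list(edit_delete("FOO")))),
               "unknown gene")
  expect_error(apply_mutant(net, mutant_spec("x", list(edit_scale("nope", 2)))),
               "unknown parameter")
})

test_that("config round-trips and the reaction export is complete", {
  tmp <- tempfile(fileext = ".yaml")
  write_config(tmp, default_params(), medium = "galactose",
               mutant = mutant_catalog()$clb5d)
  cfg <- read_config(tmp)
  expect_equal(cfg$medium$name, "galactose")
  expect_equal(cfg$network$params$ktm_CLB5, default_params()$ktm_CLB5 * 0.5)

  tsv <- tempfile(fileext = ".tsv")
  export_network_tsv(cfg$network, tsv)
  exported <- utils::read.delim(tsv)
  expect_equal(nrow(exported), length(cfg$network$reactions))
  expect_true(all(c("reactants", "products", "rate", "scaling") %in%
                    colnames(exported)))
})
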