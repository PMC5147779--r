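# Genotypes as declarative edit lists applied to the wild-type network.

#' Construct a mutant specification
#'
#' A genotype is a list of edits applied to the wild-type parameterization:
#' `delete` silences a gene's transcription, `overexpress` adds a
#' constitutive promoter at a stated rate (used for GAL- alleles, which are
#' simulated in galactose medium), `multicopy` multiplies the native
#' transcription rate, `stabilize` removes a named degradation route, and
#' `scale` multiplies a single rate constant (used for feedback-strength
#' scans).
#'
#' @param name strain label, e.g. `"cln1d cln2d"`
#' @param edits list of edits from [edit_delete()], [edit_overexpress()],
#'   [edit_multicopy()], [edit_stabilize()], [edit_scale()]
#' @return object of class `yc_mutant`
#' @export
mutant_spec <- function(name, edits = list()) {
  structure(list(name = name, edits = edits), class = "yc_mutant")
}

#' @rdname mutant_spec
#' @param gene gene name (upper case, e.g. `"CLN1"`)
#' @export
edit_delete <- function(gene) list(type = "delete", gene = gene)

#' @rdname mutant_spec
#' @param rate constitutive transcription rate of the inserted promoter
#'   (mRNA/min)
#' @export
edit_overexpress <- function(gene, rate) {
  list(type = "overexpress", gene = gene, rate = rate)
}

#' @rdname mutant_spec
#' @param factor multiplier (copy number for `multicopy`, scale factor for
#'   `scale`)
#' @export
edit_multicopy <- function(gene, factor) {
  list(type = "multicopy", gene = gene, factor = factor)
}

#' @rdname mutant_spec
#' @param protein protein whose degradation route is removed
#' @param route currently `"apc"`: removal of the destruction-box-dependent
#'   APC routes (both Cdc20- and Cdh1-mediated), leaving basal turnover
#' @export
edit_stabilize <- function(protein, route = "apc") {
  list(type = "stabilize", protein = protein, route = route)
}

#' @rdname mutant_spec
#' @param param name of a rate constant in [default_params()]
#' @export
edit_scale <- function(param, factor) {
  list(type = "scale", param = param, factor = factor)
}

#' Apply a mutant specification to a network
#'
#' Returns an edited copy of the network, rebuilt from the edited
#' parameterization in the same medium. Deletions zero the gene's
#' transcription rate (and are therefore idempotent); edits touching
#' disjoint genes/parameters commute.
#'
#' @param net wild-type (or previously edited) `yc_network`
#' @param spec a [mutant_spec()]
#' @return edited `yc_network`
#' @export
apply_mutant <- function(net, spec) {
  stopifnot(inherits(net, "yc_network"), inherits(spec, "yc_mutant"))
  p <- net$params
  geno <- net$genotype
  for (e in spec$edits) {
    switch(e$type,
      delete = {
        key <- paste0("ktm_", e$gene)
        if (is.null(p[[key]])) stop("cannot delete unknown gene ", e$gene)
        p[[key]] <- 0
        geno$overexpress <- geno$overexpress[names(geno$overexpress) != e$gene]
      },
      overexpress = {
        if (!paste0("ktm_", e$gene) %in% names(p))
          stop("cannot overexpress unknown gene ", e$gene)
        geno$overexpress[e$gene] <- e$rate
      },
      multicopy = {
        key <- paste0("ktm_", e$gene)
        if (is.null(p[[key]])) stop("cannot amplify unknown gene ", e$gene)
        p[[key]] <- p[[key]] * e$factor
      },
      stabilize = {
        if (!identical(e$protein, "Clb2"))
          stop("no stabilization route defined for ", e$protein)
        geno$clb2_db_delta <- TRUE
        p$kd20_clb2 <- 0
        p$kdh_clb2 <- 0
      },
      scale = {
        if (is.null(p[[e$param]])) stop("unknown parameter ", e$param)
        p[[e$param]] <- p[[e$param]] * e$factor
      },
      stop("unknown edit type ", e$type)
    )
  }
  geno$label <- if (is.null(geno$label) || geno$label == "wild type") {
    spec$name
  } else paste(geno$label, spec$name)
  build_wildtype(structure(p, class = "yc_params"), net$medium, geno)
}

#' Catalog of simulated strains
#'
#' Named [mutant_spec()]s for the strains studied in the package: the
#' cyclin deletions, the G1-stabilizer deletions, the stable-Clb2 allele
#' (`CLB2-dbD`, which lacks the destruction box required for APC-mediated
#' degradation), galactose-driven overexpression alleles and their
#' combinations. In the composite-variable convention, `clb5d` (single
#' deletion) halves the CLB5+CLB6 transcription rate while `clb5d clb6d`
#' silences it; likewise `cln1d`/`cln2d` each remove one of the two
#' SBF-driven CLN genes.
#'
#' @return named list of `yc_mutant` objects
#' @export
mutant_catalog <- function() {
  gal <- 2.0  # constitutive transcription rate of GAL-driven alleles
  list(
    wildtype = mutant_spec("wild type"),
    cln1d = mutant_spec("cln1d", list(edit_delete("CLN1"))),
    cln2d = mutant_spec("cln2d", list(edit_delete("CLN2"))),
    cln1d_cln2d = mutant_spec("cln1d cln2d",
      list(edit_delete("CLN1"), edit_delete("CLN2"))),
    clb5d = mutant_spec("clb5d", list(edit_scale("ktm_CLB5", 0.5))),
    clb5d_clb6d = mutant_spec("clb5d clb6d", list(edit_delete("CLB5"))),
    sic1d = mutant_spec("sic1d", list(edit_delete("SIC1"))),
    swi5d = mutant_spec("swi5d", list(edit_delete("SWI5"))),
    cdh1d = mutant_spec("cdh1d", list(edit_delete("CDH1"))),
    cln1d_cln2d_sic1d = mutant_spec("cln1d cln2d sic1d",
      list(edit_delete("CLN1"), edit_delete("CLN2"), edit_delete("SIC1"))),
    swi5d_cdh1d = mutant_spec("swi5d cdh1d",
      list(edit_delete("SWI5"), edit_delete("CDH1"))),
    clb2_dbd = mutant_spec("CLB2-dbD", list(edit_stabilize("Clb2"))),
    clb2_dbd_clb5d = mutant_spec("CLB2-dbD clb5d",
      list(edit_stabilize("Clb2"), edit_scale("ktm_CLB5", 0.5))),
    gal_clb2 = mutant_spec("GAL-CLB2", list(edit_overexpress("CLB2", gal))),
    gal_clb5 = mutant_spec("GAL-CLB5", list(edit_overexpress("CLB5", gal))),
    gal_sic1 = mutant_spec("GAL-SIC1", list(edit_overexpress("SIC1", gal))),
    multi_sic1 = mutant_spec("Multi-SIC1", list(edit_multicopy("SIC1", 4))),
    clb2_dbd_gal_sic1 = mutant_spec("CLB2-dbD GAL-SIC1",
      list(edit_stabilize("Clb2"), edit_overexpress("SIC1", gal))),
    swi5d_cdh1d_gal_sic1 = mutant_spec("swi5d cdh1d GAL-SIC1",
      list(edit_delete("SWI5"), edit_delete("CDH1"),
           edit_overexpress("SIC1", gal)))
  )
}

#' Scale the strength of the Cln1,2 -| Whi5 positive feedback loop
#'
#' Convenience spec multiplying the rate constants for Cln1,2-dependent
#' phosphorylation of Whi5 by `strength` (1 = wild type); optionally
#' compensating with a `cln3_boost` on the Cln3-dependent rate.
#'
#' @param strength multiplier on `kp_whi5_cln1` and `kp_whi5_cln2`
#' @param cln3_boost multiplier on `kp_whi5_cln3`
#' @return a `yc_mutant`
#' @export
whi5_feedback_spec <- function(strength, cln3_boost = 1) {
  mutant_spec(sprintf("Whi5 PFL x%g", strength), list(
    edit_scale("kp_whi5_cln1", strength),
    edit_scale("kp_whi5_cln2", strength),
    edit_scale("kp_whi5_cln3", cln3_boost)))
}

#' Scale the strength of the Clb2 -> Fkh2 positive feedback loop
#'
#' @param strength multiplier on `kp_fkh2_clb2`
#' @param g1s_boost multiplier on the Cln1,2,3/Clb5-dependent Fkh2
#'   phosphorylation rates
#' @return a `yc_mutant`
#' @export
fkh2_feedback_spec <- function(strength, g1s_boost = 1) {
  mutant_spec(sprintf("Fkh2 PFL x%g", strength), list(
    edit_scale("kp_fkh2_clb2", strength),
    edit_scale("kp_fkh2_cln1", g1s_boost),
    edit_scale("kp_fkh2_cln2", g1s_boost),
    edit_scale("kp_fkh2_cln3", g1s_boost),
    edit_scale("kp_fkh2_clb5", g1s_boost)))
}
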