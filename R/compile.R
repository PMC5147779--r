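# Flat array representation of a network, shared by the SSA core and the
# mass-action ODE right-hand side. Both engines read the same rate table;
# any unit mismatch between them is caught by the derivative/propensity
# consistency tests.

.scaling_code <- c(zero_order = 0L, synthesis = 1L, unimolecular = 2L,
                   bimolecular = 3L, translation = 4L, cln3_translation = 5L)

#' Compile a network into flat arrays
#'
#' @param net a `yc_network` or a bare list with `species` and `reactions`
#' @return list with species names, reactant index vectors (`r1`, `r2`;
#'   0 = none), scaling codes, rates (rate * multiplicity), a dense
#'   stoichiometry matrix (reactions x species) and a reaction->dependent
#'   reaction adjacency (used by the SSA to update propensities)
#' @export
compile_network <- function(net) {
  sp <- net$species$name
  nsp <- length(sp)
  rx <- net$reactions
  nr <- length(rx)
  r1 <- integer(nr); r2 <- integer(nr); scode <- integer(nr)
  rate <- numeric(nr)
  S <- matrix(0, nr, nsp, dimnames = list(NULL, sp))
  for (i in seq_len(nr)) {
    r <- rx[[i]]
    idx <- match(r$reactants, sp)
    if (anyNA(idx)) stop("undeclared reactant in reaction ", i)
    r1[i] <- if (length(idx) >= 1L) idx[1] else 0L
    r2[i] <- if (length(idx) >= 2L) idx[2] else 0L
    scode[i] <- .scaling_code[[r$scaling]]
    rate[i] <- r$rate * r$mult
    for (j in idx) S[i, j] <- S[i, j] - 1
    pidx <- match(r$products, sp)
    if (anyNA(pidx)) stop("undeclared product in reaction ", i)
    for (j in pidx) S[i, j] <- S[i, j] + 1
  }
  # reactions whose propensity depends on species j
  dep_sp <- vector("list", nsp)
  for (i in seq_len(nr)) {
    for (j in unique(c(r1[i], r2[i]))) {
      if (j > 0L) dep_sp[[j]] <- c(dep_sp[[j]], i)
    }
  }
  # for each reaction, the set of reactions to refresh after it fires
  dep_rxn <- vector("list", nr)
  for (i in seq_len(nr)) {
    changed <- which(S[i, ] != 0)
    dep_rxn[[i]] <- sort(unique(c(i, unlist(dep_sp[changed]))))
  }
  list(species = sp, r1 = r1, r2 = r2, scode = scode, rate = rate,
       S = S, dep_rxn = dep_rxn,
       params = net$params, medium = net$medium, index = net$index)
}

#' Propensity of one reaction
#'
#' Volume enters through the molecules-per-nM factor Omega(V) = V/1.67:
#' volume-scaled synthesis fires at k*Omega, bimolecular reactions at
#' k*N1*N2/Omega (k*N*(N-1)/(2*Omega) for homodimerization), translation at
#' k*N*(V/v_ref) and CLN3 translation at k*N*(V/v_ref)^2; per-gene-copy
#' synthesis and unimolecular steps are volume-independent.
#'
#' @param rxn a [reaction()]
#' @param state a cell state (list with `counts` named vector and `v`)
#' @param params parameter set supplying `conv` and `v_ref`
#' @return propensity in events/min
#' @export
propensity <- function(rxn, state, params = default_params()) {
  n <- state$counts
  if (any(n < 0)) stop("negative molecule count in state")
  v <- state$v
  omega <- v / params$conv
  k <- rxn$rate * rxn$mult
  switch(rxn$scaling,
    zero_order = k,
    synthesis = k * omega,
    unimolecular = k * n[[rxn$reactants[1]]],
    translation = k * n[[rxn$reactants[1]]] * (v / params$v_ref),
    cln3_translation = k * n[[rxn$reactants[1]]] * (v / params$v_ref)^2,
    bimolecular = {
      a <- rxn$reactants[1]; b <- rxn$reactants[2]
      if (a == b) k * n[[a]] * (n[[a]] - 1) / (2 * omega)
      else k * n[[a]] * n[[b]] / omega
    })
}

# vectorized propensities over a compiled network (real-valued counts
# allowed: the same expressions serve as the ODE mean-field rates)
propensities_all <- function(cnet, counts, v) {
  p <- cnet$params
  omega <- v / p$conv
  n1 <- unname(counts[pmax(cnet$r1, 1L)]); n1[cnet$r1 == 0L] <- 1
  n2 <- unname(counts[pmax(cnet$r2, 1L)]); n2[cnet$r2 == 0L] <- 1
  a <- numeric(length(cnet$rate))
  sc <- cnet$scode
  k <- cnet$rate
  a[sc == 0L] <- k[sc == 0L]
  a[sc == 1L] <- k[sc == 1L] * omega
  a[sc == 2L] <- k[sc == 2L] * n1[sc == 2L]
  bi <- sc == 3L
  homo <- bi & cnet$r1 == cnet$r2
  het <- bi & !homo
  a[het] <- k[het] * n1[het] * n2[het] / omega
  a[homo] <- k[homo] * n1[homo] * (n1[homo] - 1) / (2 * omega)
  a[sc == 4L] <- k[sc == 4L] * n1[sc == 4L] * (v / p$v_ref)
  a[sc == 5L] <- k[sc == 5L] * n1[sc == 5L] * (v / p$v_ref)^2
  a
}
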