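# Toy networks with analytic or numerically exact reference distributions.
# These validate the engine contracts (propensity scaling, stationarity,
# master-equation agreement) independently of the full cell-cycle model.

.fixture_medium <- function(mu = 0) {
  structure(list(name = "fixture", mu = mu, f_daughter = 0.5,
                 mdt = if (mu > 0) log(2) / mu else Inf, clb2_factor = 1),
            class = "yc_medium")
}

.fixture_params <- function() {
  list(conv = 1.67, v_ref = 45)
}

#' Oracle fixture networks
#'
#' Small (<= 5 species) networks with a known reference law:
#' \describe{
#'   \item{constitutive_gene}{zero-order synthesis (rate `k_t`, molecules
#'     per minute, volume-independent) with first-order decay `k_d`;
#'     stationary law Poisson(k_t/k_d).}
#'   \item{two_state_promoter}{promoter toggling at `k_on`/`k_off`,
#'     transcription `k_t` from the on state, decay `k_d`; reference
#'     distribution from a truncated chemical-master-equation solve.}
#'   \item{decay_only}{pure decay from `n0` copies; half-life ln(2)/k_d.}
#'   \item{dimerization}{A + A <-> D with rates `k_f` (nM^-1 min^-1) and
#'     `k_b`; checks the homodimer propensity k N(N-1)/(2 Omega).}
#' }
#'
#' @param kind fixture name
#' @param ... rate overrides (see above)
#' @return a network usable by both engines, with extra elements `oracle`
#'   (list describing the reference law) and `kind`
#' @export
fixture_network <- function(kind = c("constitutive_gene",
                                     "two_state_promoter", "decay_only",
                                     "dimerization"), ...) {
  kind <- match.arg(kind)
  args <- list(...)
  g <- function(name, default) args[[name]] %||% default
  net <- switch(kind,
    constitutive_gene = {
      k_t <- g("k_t", 1); k_d <- g("k_d", 0.1)
      list(species = data.frame(name = "mRNA", role = "mrna"),
           reactions = list(
             reaction(character(), "mRNA", k_t, "zero_order", group = "syn"),
             reaction("mRNA", character(), k_d, "unimolecular",
                      group = "decay")),
           init = c(mRNA = 0),
           oracle = list(type = "poisson", lambda = k_t / k_d))
    },
    two_state_promoter = {
      k_on <- g("k_on", 0.2); k_off <- g("k_off", 0.3)
      k_t <- g("k_t", 2); k_d <- g("k_d", 0.2)
      list(species = data.frame(name = c("G_off", "G_on", "mRNA"),
                                role = c("promoter", "promoter", "mrna")),
           reactions = list(
             reaction("G_off", "G_on", k_on, "unimolecular", group = "prom"),
             reaction("G_on", "G_off", k_off, "unimolecular", group = "prom"),
             reaction("G_on", c("G_on", "mRNA"), k_t, "unimolecular",
                      group = "syn"),
             reaction("mRNA", character(), k_d, "unimolecular",
                      group = "decay")),
           init = c(G_off = 1, G_on = 0, mRNA = 0),
           oracle = list(type = "cme",
                         rates = c(k_on = k_on, k_off = k_off, k_t = k_t,
                                   k_d = k_d)))
    },
    decay_only = {
      k_d <- g("k_d", 0.1); n0 <- g("n0", 1000)
      list(species = data.frame(name = "X", role = "protein"),
           reactions = list(
             reaction("X", character(), k_d, "unimolecular",
                      group = "decay")),
           init = c(X = n0),
           oracle = list(type = "half_life", value = log(2) / k_d))
    },
    dimerization = {
      k_f <- g("k_f", 0.01); k_b <- g("k_b", 0.5); n0 <- g("n0", 200)
      list(species = data.frame(name = c("A", "D"),
                                role = c("protein", "complex")),
           reactions = list(
             reaction(c("A", "A"), "D", k_f, "bimolecular", group = "dim"),
             reaction("D", c("A", "A"), k_b, "unimolecular", group = "dim")),
           init = c(A = n0, D = 0),
           oracle = list(type = "mass_action_equilibrium",
                         rates = c(k_f = k_f, k_b = k_b, n0 = n0)))
    })
  net$params <- .fixture_params()
  net$medium <- .fixture_medium(g("mu", 0))
  net$genotype <- list(overexpress = numeric(), clb2_db_delta = FALSE,
                       label = paste0("fixture:", kind))
  net$index <- NULL
  net$kind <- kind
  class(net) <- "yc_network"
  net
}

#' Stationary distribution of the two-state promoter by master equation
#'
#' Solves the truncated chemical master equation (promoter state x mRNA
#' copy number up to `n_max`) for its stationary distribution by a linear
#' solve, and returns the mRNA marginal.
#'
#' @param net a `two_state_promoter` [fixture_network()]
#' @param n_max mRNA truncation (default: mean + 10 sd of the on-state
#'   Poisson)
#' @return numeric vector of stationary probabilities for 0..n_max copies
#' @export
two_state_cme <- function(net, n_max = NULL) {
  stopifnot(identical(net$kind, "two_state_promoter"))
  r <- net$oracle$rates
  if (is.null(n_max)) {
    lam <- r[["k_t"]] / r[["k_d"]]
    n_max <- ceiling(lam + 10 * sqrt(lam) + 5)
  }
  nn <- n_max + 1L
  id <- function(gene_on, m) gene_on * nn + m + 1L  # states: (g, m)
  A <- matrix(0, 2 * nn, 2 * nn)
  for (gon in 0:1) for (m in 0:n_max) {
    i <- id(gon, m)
    # promoter switching
    if (gon == 0) { A[id(1, m), i] <- A[id(1, m), i] + r[["k_on"]]
                    A[i, i] <- A[i, i] - r[["k_on"]] }
    else { A[id(0, m), i] <- A[id(0, m), i] + r[["k_off"]]
           A[i, i] <- A[i, i] - r[["k_off"]] }
    # transcription (on state only), reflecting at the truncation
    if (gon == 1 && m < n_max) { A[id(1, m + 1), i] <- A[id(1, m + 1), i] + r[["k_t"]]
                                 A[i, i] <- A[i, i] - r[["k_t"]] }
    # decay
    if (m > 0) { A[id(gon, m - 1), i] <- A[id(gon, m - 1), i] + m * r[["k_d"]]
                 A[i, i] <- A[i, i] - m * r[["k_d"]] }
  }
  # stationary vector: A p = 0, sum p = 1
  A[1, ] <- 1
  b <- c(1, rep(0, 2 * nn - 1))
  p <- solve(A, b)
  marg <- p[id(0, 0:n_max)] + p[id(1, 0:n_max)]
  pmax(marg, 0) / sum(pmax(marg, 0))
}
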