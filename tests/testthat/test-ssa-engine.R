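# Stochastic engine: conversion, propensity laws, exactness against
# analytic and master-equation oracles, determinism.

test_that("count/concentration conversion matches C = 1.67 N/V", {
  expect_equal(count_to_conc(3000, 50), 100.2)       # ~100 nM at 50 fL
  expect_equal(conc_to_count(100, 50), 2994)         # ~3000 molecules
  expect_equal(count_to_conc(0, 37), 0)
  expect_equal(count_to_conc(1, 1.67), 1)
  expect_equal(conc_to_count(count_to_conc(1234, 42), 42), 1234)
  expect_error(count_to_conc(10, 0), "positive")
  expect_error(conc_to_count(10, -1), "positive")
})

test_that("propensities follow the volume-scaling laws", {
  p <- default_params()
  st <- cell_state(c(A = 100, B = 50, M = 7), v = 30)
  omega <- 30 / p$conv

  expect_equal(propensity(reaction(character(), "A", 2, "zero_order"), st, p), 2)
  expect_equal(propensity(reaction(character(), "A", 2, "synthesis"), st, p),
               2 * omega)
  expect_equal(propensity(reaction("A", character(), 0.1, "unimolecular"), st, p),
               10)
  expect_equal(propensity(reaction(c("A", "B"), "C", 0.05, "bimolecular"), st, p),
               0.05 * 100 * 50 / omega)
  expect_equal(propensity(reaction(c("A", "A"), "D", 0.05, "bimolecular"), st, p),
               0.05 * 100 * 99 / (2 * omega))
  b0 <- cell_state(c(A = 0, B = 50, M = 7), v = 30)
  expect_equal(propensity(reaction(c("A", "B"), "C", 1, "bimolecular"), b0, p), 0)

  # ordinary translation is proportional to V; CLN3 translation to V^2,
  # so doubling V doubles CLN3 translation relative to ordinary translation
  tr <- reaction("M", c("M", "A"), 3, "translation")
  c3 <- reaction("M", c("M", "A"), 3, "cln3_translation")
  ratio1 <- propensity(c3, st, p) / propensity(tr, st, p)
  st2 <- st; st2$v <- 60
  ratio2 <- propensity(c3, st2, p) / propensity(tr, st2, p)
  expect_equal(ratio2 / ratio1, 2)
  expect_equal(propensity(tr, st2, p) / propensity(tr, st, p), 2)

  expect_error(propensity(tr, cell_state(c(A = 1, B = 1, M = 1), v = 30) |>
                            (\(s) { s$counts[1] <- -1; s })(), p),
               "negative")
})

test_that("network with zero live reactions leaves counts constant while V grows", {
  net <- fixture_network("decay_only", k_d = 0.1, n0 = 0, mu = 0.007)
  sim <- simulate_cell(net, t_end = 100, seed = 1, sample_dt = 10,
                       stop_at_division = FALSE)
  expect_true(all(sim$trajectory[, "X"] == 0))
  expect_equal(sim$state$v, 30 * exp(0.007 * 100), tolerance = 1e-3)
})

test_that("constitutive birth-death fixture is stationary Poisson", {
  # k_t = 1/min, half-life 6.93 min => k_d = 0.1/min => Poisson(10)
  net <- fixture_network("constitutive_gene", k_t = 1, k_d = 0.1)
  expect_equal(net$oracle$lambda, 10)
  x <- fixture_samples(net, n = 4000, spacing = 25, burn = 100, seed = 42,
                       species = "mRNA")
  expect_equal(mean(x), 10, tolerance = 0.05)
  expect_equal(var(x), 10, tolerance = 0.15)
  # chi-square GOF against Poisson(10), pooled tails
  ks <- 0:25
  pk <- dpois(ks, 10); pk[length(pk)] <- 1 - ppois(24, 10)
  obs <- tabulate(pmin(x, 25) + 1, nbins = 26)
  keep <- pk * length(x) >= 5
  chi <- sum((obs[keep] - length(x) * pk[keep])^2 / (length(x) * pk[keep]))
  pval <- pchisq(chi, df = sum(keep) - 1, lower.tail = FALSE)
  expect_gt(pval, 0.01)
})

test_that("two-state promoter matches the truncated master-equation solve", {
  net <- fixture_network("two_state_promoter")
  pref <- two_state_cme(net)
  x <- fixture_samples(net, n = 12000, spacing = 12, burn = 100, seed = 7,
                       species = "mRNA")
  emp <- tabulate(pmin(x, length(pref) - 1) + 1, nbins = length(pref)) /
    length(x)
  tv <- sum(abs(emp - pref)) / 2
  expect_lt(tv, 0.02)
})

test_that("SSA sample means converge to the ODE solution with system size", {
  # mean-field convergence: scale a birth-death system up by volume
  dev <- sapply(c(1, 10), function(scale) {
    net <- fixture_network("constitutive_gene", k_t = 2 * scale, k_d = 0.1)
    x <- fixture_samples(net, n = 800, spacing = 25, burn = 100, seed = 11,
                         species = "mRNA")
    abs(mean(x) - 20 * scale) / (20 * scale)
  })
  expect_lt(dev[2], dev[1] + 0.02)  # relative deviation shrinks (or stays tiny)
  expect_lt(dev[2], 0.05)
})

test_that("derivatives equal stoichiometry-weighted propensities (shared rate table)", {
  # brute-force oracle computed reaction-by-reaction with its own formulas
  for (kind in c("two_state_promoter", "dimerization")) {
    net <- fixture_network(kind)
    st <- cell_state(net$init + 3, v = 41)
    d <- derivatives(net, st)
    expected <- stats::setNames(numeric(nrow(net$species)), net$species$name)
    for (r in net$reactions) {
      a <- propensity(r, st, default_params())
      for (sp in r$reactants) expected[sp] <- expected[sp] - a
      for (sp in r$products) expected[sp] <- expected[sp] + a
    }
    expect_equal(d$dcounts, expected, tolerance = 1e-9)
  }
  # and on the full model state
  net <- strain_network()
  st <- cell_state(net$init, v = 30)
  d <- derivatives(net, st)
  cnet <- compile_network(net)
  a <- propensities_all(cnet, st$counts, st$v)
  expect_equal(unname(d$dcounts), as.vector(a %*% cnet$S), tolerance = 1e-9)
})

test_that("identical seeds give bit-identical trajectories; different seeds differ", {
  ready <- ssa_compile(strain_network())
  s1 <- simulate_cell(ready, t_end = 150, seed = 5, cell_id = 3, sample_dt = 5)
  s2 <- simulate_cell(ready, t_end = 150, seed = 5, cell_id = 3, sample_dt = 5)
  expect_identical(s1$trajectory, s2$trajectory)
  expect_identical(s1$state$counts, s2$state$counts)
  expect_identical(s1$t_div, s2$t_div)
  s3 <- simulate_cell(ready, t_end = 150, seed = 5, cell_id = 4, sample_dt = 5)
  expect_false(identical(s1$state$counts, s3$state$counts))
})

test_that("counts stay non-negative and integral through a full-model cycle", {
  sim <- simulate_cell(strain_network(), t_end = 200, seed = 9,
                       sample_dt = 2)
  tr <- sim$trajectory[, -(1:4)]
  expect_true(all(tr >= 0))
  expect_true(all(tr == round(tr)))
})
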