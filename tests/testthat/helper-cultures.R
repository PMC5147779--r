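# Shared, lazily built simulation products. Cultures are expensive, so the
# suite builds each once (fixed seeds, sizes chosen for stable orderings at
# modest cost) and reuses it across test files.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

strain_network <- function(strain = "wildtype", medium = "glucose") {
  memo(paste("net", strain, medium), {
    net <- build_wildtype(medium = medium_growth(medium))
    if (strain != "wildtype") {
      net <- apply_mutant(net, mutant_catalog()[[strain]])
    }
    net
  })
}

wt_culture <- function(n = 40, seed = 101) {
  memo(paste("wt", n, seed),
       run_culture(strain_network(), culture_config(max_cells = n,
                                                    seed = seed)))
}

# tiny independent SSA helper: stationary samples of a fixture network
fixture_samples <- function(net, n, spacing, burn, seed, species) {
  sim <- simulate_cell(net, t_end = burn + n * spacing, seed = seed,
                       sample_dt = spacing, stop_at_division = FALSE)
  tr <- sim$trajectory
  tr[tr[, "t"] > burn, species]
}
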