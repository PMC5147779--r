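# Asymmetric division, molecule partitioning, birth-ordered culture
# scheduling, pedigree accounting.

test_that("proportional division partitions by size fraction with Cln3 at 25%", {
  net <- strain_network()
  counts <- stats::setNames(numeric(nrow(net$species)), net$species$name)
  counts["Whi5_P0"] <- 10
  counts["Cln3"] <- 100
  counts["mRNA_CLN2"] <- 7
  st <- cell_state(counts, v = 60)
  prog <- divide_cell(net, st, f = 0.4)
  expect_equal(prog$daughter$counts[["Whi5_P0"]], 4)   # round(0.4 * 10)
  expect_equal(prog$mother$counts[["Whi5_P0"]], 6)
  expect_equal(prog$daughter$counts[["Cln3"]], 25)     # 25% to daughter
  expect_equal(prog$mother$counts[["Cln3"]], 75)
  expect_equal(prog$daughter$v, 24)
  expect_equal(prog$mother$v, 36)
  expect_error(divide_cell(net, st, f = 1.2), "\\(0, 1\\)")
})

test_that("both division modes conserve molecules and volume exactly", {
  net <- strain_network()
  st <- cell_state(net$init, v = 55)
  set.seed(5)
  for (mode in c("proportional", "binomial")) {
    prog <- divide_cell(net, st, f = 0.36, mode = mode)
    mol <- net$species$role != "promoter"
    expect_equal(prog$mother$counts[mol] + prog$daughter$counts[mol],
                 st$counts[mol])
    expect_equal(prog$mother$v + prog$daughter$v, st$v)
    # the genome is copied, not split
    prom <- net$species$role == "promoter"
    expect_equal(prog$mother$counts[prom], st$counts[prom])
    expect_equal(prog$daughter$counts[prom], st$counts[prom])
  }
})

test_that("binomial partitioning has Binomial(N, f) moments", {
  net <- strain_network()
  counts <- stats::setNames(numeric(nrow(net$species)), net$species$name)
  counts["Whi5_P0"] <- 100
  st <- cell_state(counts, v = 50)
  set.seed(99)
  draws <- replicate(20000,
    divide_cell(net, st, f = 0.4, mode = "binomial")$daughter$counts[["Whi5_P0"]])
  expect_equal(mean(draws), 40, tolerance = 0.01)      # N f
  expect_equal(var(draws), 24, tolerance = 0.05)       # N f (1-f)
  expect_true(all(draws >= 0 & draws <= 100))
})

test_that("max_cells = 1 yields only the founder's record", {
  tab <- run_culture(strain_network(),
                     culture_config(max_cells = 1, seed = 3))
  expect_equal(nrow(tab), 1)
  expect_equal(tab$md_label, "founder")
  expect_true(is.na(tab$parent_id))
})

test_that("culture pedigree accounting balances divisions and cells", {
  tab <- wt_culture()
  divided <- sum(tab$arrest == "none")
  # each completed division contributes one extra live cell
  cs <- culture_count_series(tab)
  expect_equal(max(cs$n_cells), 1 + divided)
  # cells are processed in birth order
  expect_true(all(diff(tab$t_birth) >= 0))
  # every non-founder's parent divided at the child's birth time
  kids <- tab[tab$md_label != "founder", ]
  for (i in seq_len(nrow(kids))) {
    par <- tab[tab$cell_id == kids$parent_id[i], ]
    if (nrow(par)) {
      expect_equal(kids$t_birth[i], par$t_birth + par$T_div,
                   tolerance = 1e-9, ignore_attr = TRUE)
    }
  }
  # arrested cells never have progeny
  arrested_ids <- tab$cell_id[tab$arrest != "none"]
  expect_false(any(tab$parent_id %in% arrested_ids))
})

test_that("daughters are born smaller and wait longer before Start than mothers", {
  tab <- wt_culture()
  done <- tab[tab$arrest == "none" & tab$md_label != "founder", ]
  d <- done[done$md_label == "daughter", ]
  m <- done[done$md_label == "mother", ]
  expect_gt(nrow(d), 8)
  expect_lt(mean(d$V_bir), mean(m$V_bir))
  expect_gt(mean(d$T_unbud, na.rm = TRUE), mean(m$T_unbud, na.rm = TRUE))
})

test_that("reruns with the same master seed are identical", {
  t1 <- run_culture(strain_network(), culture_config(max_cells = 6, seed = 17))
  t2 <- run_culture(strain_network(), culture_config(max_cells = 6, seed = 17))
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  t3 <- run_culture(strain_network(), culture_config(max_cells = 6, seed = 18))
  expect_false(identical(as.data.frame(t1), as.data.frame(t3)))
})

test_that("extant population returns exactly the cells alive at t_stop", {
  tab <- wt_culture()
  expect_equal(nrow(extant_population(tab, -5)), 0)
  t_first_div <- tab$t_birth[1] + tab$T_div[1]
  early <- extant_population(tab, t_first_div / 2)
  expect_equal(early$cell_id, 1L)      # only the founder before it divides
  mid <- max(tab$t_birth) * 0.8
  ext <- extant_population(tab, mid)
  expect_true(all(ext$t_birth < mid))
  expect_true(all(ext$t_birth + ext$T_div > mid))
  # every extant cell is alive at t_stop: intervals cover the instant once
  expect_equal(anyDuplicated(ext$cell_id), 0)
})

test_that("gaussian division-fraction noise stays within the truncation guards", {
  net <- strain_network()
  tab <- run_culture(net, culture_config(max_cells = 8, seed = 23,
                                         f_cv = 0.10))
  kids <- tab[tab$md_label == "daughter", ]
  par <- tab[match(kids$parent_id, tab$cell_id), ]
  f_obs <- kids$V_bir / par$V_div
  expect_true(all(f_obs > 0.05 & f_obs < 0.95))
  expect_gt(stats::sd(f_obs), 0)  # noise is actually applied
})
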