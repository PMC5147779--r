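# Milestone scoring: indicators, division detection, Whi5 localization,
# activation times, arrest classification, duration identities.

test_that("indicators decay without cyclins and reach the first-order fixed point", {
  net <- strain_network()
  p <- net$params
  st <- cell_state(net$init * 0 + net$init * 0, v = 30, bud_ss = 12,
                   dna_ss = 7)
  st$counts[] <- 0  # no cyclins at all
  s1 <- update_indicators(net, st, dt = 5)
  expect_lt(s1$bud_ss, st$bud_ss)
  expect_lt(s1$dna_ss, st$dna_ss)
  s2 <- update_indicators(net, s1, dt = 500)
  expect_equal(s2$bud_ss, 0, tolerance = 1e-6)

  # constant cyclin input c with unit efficiency -> bud_ss = ks/kd * c
  st$counts["Cln1"] <- conc_to_count(50, 30)  # 50 nM
  sfix <- update_indicators(net, st, dt = 1e4)
  expect_equal(sfix$bud_ss,
               p$ks_bud * p$eff_bud_cln1 * count_to_conc(st$counts["Cln1"], 30) /
                 p$kd_bud,
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("division detector requires arming and fires on downward crossings", {
  t <- seq(0, 300, by = 0.5)
  # never armed: constant 5 nM
  expect_length(detect_division(t, rep(5, length(t))), 0)
  # one pulse: rise to 300, fall through 12.5
  pulse <- 300 * exp(-((t - 100) / 30)^2)
  d1 <- detect_division(t, pulse)
  expect_length(d1, 1)
  expect_gt(d1, 100)
  # two full pulses -> exactly two divisions (brute-force synthetic scan)
  two <- 300 * (exp(-((t - 80) / 20)^2) + exp(-((t - 220) / 20)^2))
  expect_length(detect_division(t, two), 2)
  # sub-arming oscillation between 13 and 24 never fires
  wig <- 18.5 + 5.5 * sin(t / 5)
  expect_length(detect_division(t, wig), 0)
})

test_that("nuclear Whi5 sums the <= 2-phosphate forms, free and SBF-bound", {
  net <- strain_network()
  st <- cell_state(stats::setNames(numeric(nrow(net$species)),
                                   net$species$name), v = 50)
  st$counts["Whi5_P0"] <- 9000
  expect_equal(whi5_nuclear(net, st$counts, 50), 1.67 * 9000 / 50)  # ~300 nM
  expect_gt(whi5_nuclear(net, st$counts, 50), 200)                  # no exit yet
  # bound Whi5P2:SBF counts toward the nuclear pool
  st$counts["Whi5_P0"] <- 0
  st$counts["Whi5P2_SBF"] <- 1000
  expect_equal(whi5_nuclear(net, st$counts, 50), 1.67 * 1000 / 50)
  # forms with >= 3 phosphates do not
  st$counts["Whi5P2_SBF"] <- 0
  st$counts["Whi5_P3"] <- 5000
  st$counts["Whi5_P10"] <- 5000
  expect_equal(whi5_nuclear(net, st$counts, 50), 0)
})

test_that("gene activation is the first upward threshold crossing", {
  t <- 0:100
  act <- cbind(CLN2 = ifelse(t >= 20, 1, 0), CLB2 = rep(0, 101))
  th <- c(CLN2 = 0.15, CLB2 = 0.2)
  res <- gene_activation_times(t, act, th)
  expect_equal(res[["CLN2"]], 20)
  expect_true(is.na(res[["CLB2"]]))
})

test_that("arrest labels partition non-dividing cells (decision table)", {
  expect_equal(classify_arrest(TRUE, TRUE, TRUE), "none")
  expect_equal(classify_arrest(TRUE, FALSE, FALSE), "none")
  expect_equal(classify_arrest(FALSE, FALSE, FALSE), "unbudded")
  expect_equal(classify_arrest(FALSE, FALSE, TRUE), "unbudded")
  expect_equal(classify_arrest(FALSE, TRUE, FALSE), "unreplicated")
  expect_equal(classify_arrest(FALSE, TRUE, TRUE), "m_phase")
  # exactly one label for every flag combination
  for (b in c(TRUE, FALSE)) for (dn in c(TRUE, FALSE)) {
    expect_length(classify_arrest(FALSE, b, dn), 1)
  }
})

test_that("duration identities hold exactly for every non-arrested cell", {
  tab <- wt_culture()
  done <- tab[tab$arrest == "none", ]
  expect_gt(nrow(done), 10)
  expect_equal(done$T_div, done$T_unbud + done$T_bud, tolerance = 1e-12)
  expect_equal(done$T_div, done$T_g1 + done$T_sg2m, tolerance = 1e-12)
  expect_true(all(done$T_unbud != done$T_g1))  # distinct milestones
  expect_true(all(done[c("T_unbud", "T_g1", "T_bud", "T_sg2m", "T_div")] >= 0))
})

test_that("event detection is stable to trajectory sampling cadence", {
  t_fine <- seq(0, 300, by = 0.25)
  pulse <- function(t) 300 * exp(-((t - 150) / 40)^2)
  d_fine <- detect_division(t_fine, pulse(t_fine))
  t_coarse <- seq(0, 300, by = 2)
  d_coarse <- detect_division(t_coarse, pulse(t_coarse))
  expect_equal(length(d_fine), length(d_coarse))
  expect_lt(abs(d_fine - d_coarse), 2)  # within one coarse interval
})
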