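# Representative supply points in the three regimes (no2_in = 25 uM N):
# rho = 0.06 (OM-limited), 0.18 (co-limited), 0.30 (NO2- limited).

test_that("regime classification matches consumption-vector geometry", {
  ss_lo <- steady_state(nf_comm, om_in = 0.06 * 25, no2_in = 25)
  r_lo <- classify_regime(ss_lo, nf_comm)
  expect_equal(r_lo$regime, "denit+anammox")
  expect_equal(r_lo$predicted_regime, "denit")
  expect_true(r_lo$no2_accumulates)   # insufficient electron donor
  expect_false(r_lo$om_accumulates)

  ss_mid <- steady_state(nf_comm, om_in = 0.18 * 25, no2_in = 25)
  r_mid <- classify_regime(ss_mid, nf_comm)
  expect_equal(r_mid$regime, "denit+DNRA coexistence")
  expect_equal(r_mid$predicted_regime, "coexist")
  expect_false(r_mid$om_accumulates)  # both resources limit growth
  expect_false(r_mid$no2_accumulates)

  ss_hi <- steady_state(nf_comm, om_in = 0.30 * 25, no2_in = 25)
  r_hi <- classify_regime(ss_hi, nf_comm)
  expect_equal(r_hi$regime, "DNRA-only")
  expect_equal(r_hi$predicted_regime, "dnra")
  expect_true(r_hi$om_accumulates)    # insufficient electron acceptor
  expect_true(r_hi$nh4_accumulates)   # ammonification dominates
})

test_that("transect reproduces the regime sequence and nitrite fate", {
  fx <- fixture_bundle("integration")$`transect-9pt`
  tr <- transect(nf_comm, om_in = fx$om_in, no2_in = fx$no2_in)
  expect_true(all(tr$converged))
  bounds <- fx$expected$boundary_rho
  # off-boundary points: simulated survival matches the CV prediction
  off <- purrr::map_lgl(seq_len(nrow(tr)), function(i) {
    all(abs(tr$rho[i] - bounds) > 0.015)
  })
  sim_regime <- dplyr::case_when(
    tr$b_dnra > 0 & tr$b_denit1 > 0 ~ "coexist",
    tr$b_dnra > 0 ~ "dnra",
    TRUE ~ "denit")
  expect_equal(sim_regime[off], tr$predicted_regime[off])
  # fate fractions normalize wherever nitrite is being consumed
  act <- tr$active
  expect_true(all(abs(tr$f_dnra[act] + tr$f_denit[act] + tr$f_anammox[act] - 1)
                  < 1e-9))
  # DNRA absent at the OM-limited end, present at the NO2--limited end
  expect_equal(tr$b_dnra[1], 0)
  expect_gt(tr$b_dnra[nrow(tr)], 0)
  # monotone structure along the supply-ratio axis
  expect_true(all(diff(tr$b_dnra) > -1e-8))
  ratio <- tr$n2_production / tr$nh4_production
  expect_true(all(diff(ratio) < 1e-8))
  # ammonium regeneration dominates loss at the high-ratio end
  expect_gt(tr$nh4_production[nrow(tr)], tr$n2_production[nrow(tr)])
  # anammox only persists in the OM-limited regime
  expect_equal(tr$b_anammox[off] > 0, tr$predicted_regime[off] == "denit")
})

test_that("nitrite fate is invariant to uniform supply rescaling", {
  a <- steady_state(nf_comm, om_in = 4.5, no2_in = 25)
  b <- steady_state(nf_comm, om_in = 9.0, no2_in = 50)
  fa <- nitrite_fate(a)
  fb <- nitrite_fate(b)
  # approximate invariance: the R* offsets in the balances do not rescale
  expect_equal(fa$f_dnra, fb$f_dnra, tolerance = 0.05)
  expect_equal(fa$f_denit, fb$f_denit, tolerance = 0.05)
  # absolute fluxes scale with the supply
  expect_equal(fb$no2_flux_total / fa$no2_flux_total, 2, tolerance = 1e-2)
})

test_that("analytic net-zero ratio is the mean of the consumption vectors", {
  # independent arithmetic from the printed-budget anchors
  eeq <- 29.1
  x_dnra <- (35.5 + 1 + 20 / 6) / (1 + eeq / 6)
  fs_dnra <- 20 / (eeq * x_dnra)
  fs_den <- 20 / (eeq * 27.5 / 6.6)
  rho_mid <- 0.5 * (6 / (eeq * (1 - fs_dnra)) + 3 / (eeq * (1 - fs_den)))
  expect_equal(net_zero_analytic(0.25), rho_mid, tolerance = 1e-10)
  expect_equal(net_zero_analytic(0.25), 0.17640, tolerance = 1e-4)
  # step-1 mode replaces 3 respired electrons by 2
  expect_equal(net_zero_analytic(0.25, mode = "step1"),
               0.5 * (6 / (eeq * (1 - fs_dnra)) + 2 / (eeq * (1 - fs_den))),
               tolerance = 1e-10)
  # the baseline endpoints bracket the reported interval (within 0.005)
  expect_lt(abs(net_zero_analytic(0.2) - 0.1729), 0.005)
  expect_lt(abs(net_zero_analytic(0.3) - 0.1820), 0.005)
})

test_that("numeric net-zero balance agrees with the analytic ratio", {
  nz <- net_zero_numeric(nf_comm, no2_in = 25, interval = c(0.14, 0.22),
                         n_scan = 5)
  expect_lt(abs(nz$rho - net_zero_analytic(0.25)), 0.005)
  # strictly inside the coexistence window bounded by the CVs
  expect_gt(nz$rho, pathway_cv(nf_comm))
  expect_lt(nz$rho, consumption_vector(nf_comm$types$dnra))
  rec <- nz$record
  # anammox is excluded at the balance point
  expect_equal(unname(rec$biomass[["anammox"]]), 0)
  # equal nitrite reduction by the two heterotroph pathways
  fate <- nitrite_fate(rec)
  expect_equal(fate$f_dnra, fate$f_denit, tolerance = 1e-3)
  # DNRA biomass is close to the combined denitrification biomass
  ratio <- rec$biomass[["dnra"]] /
    (rec$biomass[["denit1"]] + rec$biomass[["denit2"]])
  expect_gt(ratio, 0.8)
  expect_lt(ratio, 1.4)
  # alternative balance (total NH4+ production = total N2-N production)
  nz2 <- net_zero_numeric(nf_comm, no2_in = 25, balance = "nh4-vs-n2",
                          interval = c(0.14, 0.22), n_scan = 5)
  expect_lt(abs(nz2$rho - net_zero_analytic(0.25)), 0.005)
})

test_that("anammox contribution is zero outside its niche", {
  ss <- steady_state(nf_comm, om_in = 7.5, no2_in = 25)  # DNRA-only
  ac <- anammox_contribution(ss)
  expect_equal(ac$pct_no2_uptake, 0)
  expect_equal(ac$pct_n2_production, 0)
  expect_false(ac$active)
})

test_that("three-type equilibrium exists only under the superior-anammox trait ordering", {
  # default ordering: no supply ratio admits a four-population equilibrium
  expect_equal(nrow(three_type_window(nf_comm, rho = seq(0.04, 0.24, 0.02))), 0)
  sup <- scenario("anammox-superior")$community
  w <- three_type_window(sup, rho = seq(0.06, 0.12, 0.005))
  expect_gt(nrow(w), 0)
  expect_true(all(w$rho > 0.06 & w$rho < 0.11))
  eq <- three_type_equilibrium(sup, om_in = 2.04, no2_in = 25)
  expect_true(eq$feasible)
  # the solved equilibrium balances every resource: verify by evaluating the
  # full derivative field at the reconstructed state
  cfg <- chemostat_config(om_in = 2.04, no2_in = 25)
  x <- c(dnra = eq$b_dnra, denit1 = eq$b_denit1, denit2 = eq$b_denit2,
         anammox = eq$b_anammox, om = eq$om, no2 = eq$no2, nh4 = eq$nh4,
         n2o_n = eq$n2o_n, n2_n = 0, no3 = 0, dic = cfg$dic_in)
  dx <- chemostat_derivatives(x, cfg, sup)
  core <- c("dnra", "denit1", "denit2", "anammox", "om", "no2", "nh4", "n2o_n")
  expect_true(all(abs(dx[core]) < 1e-8))
})
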