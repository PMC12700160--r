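test_that("growth rate follows Liebig's law of the minimum", {
  dnra <- nf_comm$types$dnra
  sat <- c(om = 1e9, no2 = 1e9)
  expect_equal(growth_rate(dnra, sat), min(dnra$yields * nf_v),
               tolerance = 1e-6)
  # the limiting term at half saturation gives half its maximal rate
  half <- c(om = 1e9, no2 = dnra$kinetics$k[["no2"]])
  expect_equal(growth_rate(dnra, half), dnra$yields[["no2"]] * nf_v / 2,
               tolerance = 1e-6)
  expect_equal(growth_rate(dnra, c(om = 0, no2 = 10)), 0)
  expect_error(growth_rate(dnra, c(om = 1)), "no2")
})

test_that("limiting resource is the argmin with canonical tie-break", {
  dnra <- nf_comm$types$dnra
  expect_equal(limiting_resource(dnra, c(om = 0.01, no2 = 50)), "om")
  expect_equal(limiting_resource(dnra, c(om = 50, no2 = 0.001)), "no2")
  # exact tie between both terms breaks to the canonical first resource (OM):
  # a budget with equal OM and acceptor coefficients plus equal kinetics
  # makes the two Monod terms identical at equal concentrations
  fs_sym <- 1 - 6 / 29.1
  b_sym <- heterotroph_budget("NO2->NH4", fs_sym)
  expect_equal(b_sym$om, b_sym$no2, tolerance = 1e-12)
  ft_sym <- functional_type(
    b_sym, kinetics = list(v_max = 40, k = c(om = 0.5, no2 = 0.5)), d = 0.1)
  expect_equal(limiting_resource(ft_sym, c(om = 2, no2 = 2)), "om")
  amx <- nf_comm$types$anammox
  expect_equal(limiting_resource(amx, c(no2 = 100, nh4 = 1e-4)), "nh4")
})

test_that("subsistence concentration matches the growth-balance definition", {
  # at R = R* (other resources saturated) growth equals the loss rate
  for (ft in nf_comm$types) {
    for (res in ft$required) {
      rstar <- subsistence_concentration(ft, res)
      conc <- setNames(rep(1e9, length(ft$required)), ft$required)
      conc[res] <- rstar
      expect_equal(growth_rate(ft, conc), ft$d, tolerance = 1e-10)
    }
  }
  # closed form vs numerical root of the Monod balance, randomized
  set.seed(77)
  for (i in 1:20) {
    y <- runif(1, 0.01, 0.4)
    v <- runif(1, 5, 100)
    k <- runif(1, 0.01, 5)
    d <- runif(1, 0.02, min(0.5, 0.9 * y * v))
    b <- heterotroph_budget("NO2->N2O", calibrate_fs(y))
    ft <- functional_type(b, kinetics = list(v_max = v, k = c(om = k, no2 = k)),
                          d = d)
    num <- uniroot(function(r) y * v * r / (r + k) - d,
                   c(1e-12, 1e6), tol = 1e-14)$root
    expect_equal(subsistence_concentration(ft, "om"), c(om = num),
                 tolerance = 1e-6)
  }
})

test_that("R* is decreasing in yield and v_max, increasing in K and d", {
  base <- list(y = 0.1, v = 40, k = 0.05, d = 0.1)
  rstar <- function(y, v, k, d) k * d / (y * v - d)
  with(base, {
    expect_true(all(diff(rstar(seq(0.05, 0.3, 0.05), v, k, d)) < 0))
    expect_true(all(diff(rstar(y, seq(20, 80, 10), k, d)) < 0))
    expect_true(all(diff(rstar(y, v, seq(0.01, 0.2, 0.02), d)) > 0))
    expect_true(all(diff(rstar(y, v, k, seq(0.05, 0.5, 0.05))) > 0))
  })
  # package trait orderings under shared kinetics
  rs <- function(met, res) nf_traits$rstar[nf_traits$metabolism == met &
                                             nf_traits$resource == res]
  expect_lt(rs("denit1", "om"), rs("dnra", "om"))
  expect_lt(rs("dnra", "no2"), rs("denit1", "no2"))
})

test_that("kinetics calibration solves and round-trips the R* anchors", {
  # rounded trait-table inputs (an ill-conditioned but solvable system)
  fit <- calibrate_kinetics_from_rstar(y = c(0.034, 0.0195),
                                       rstar = c(0.0043, 0.00775), d = 0.1)
  expect_equal(fit$v_max, 70.0508, tolerance = 1e-4)
  # round trip: the recovered kinetics regenerate both R* anchors
  regen <- fit$k * 0.1 / (c(0.034, 0.0195) * fit$v_max - 0.1)
  expect_equal(regen, c(0.0043, 0.00775), tolerance = 1e-9)
  expect_error(
    calibrate_kinetics_from_rstar(y = c(0.02, 0.02),
                                  rstar = c(0.004, 0.008), d = 0.1),
    "infeasible")
  # package defaults: exact-yield calibration
  kin <- default_kinetics()
  regen2 <- kin$k[["no2"]] * 0.1 /
    (c(nf_comm$budgets$y_n[1:2]) * kin$v_max - 0.1)
  expect_equal(regen2, c(0.0043, 0.00775), tolerance = 1e-9)
  # independent check: the OM* anchor predicts the denitrifier OM* midpoint
  expect_equal(nf_traits$rstar[nf_traits$metabolism == "denit1" &
                                 nf_traits$resource == "om"],
               0.061, tolerance = 0.01)
})

test_that("consumption vectors order DNRA above denitrification", {
  expect_equal(consumption_vector(nf_comm$types$dnra),
               6.8091168 / 29.6908832, tolerance = 1e-6)
  expect_equal(consumption_vector(nf_comm$types$denit1),
               (27.5 / 6.6) / 50.625, tolerance = 1e-10)
  # full-pathway closed form: 3 respired electrons per N
  expect_equal(consumption_vector(nf_comm$types$denit1, "full"),
               3 / (29.1 * (1 - 0.16494845)), tolerance = 1e-6)
  expect_gt(consumption_vector(nf_comm$types$dnra), pathway_cv(nf_comm))
  # at any common fs, 6 vs 2 accepted electrons per N fix the cv ratio at 3
  for (fs in seq(0.05, 0.9, by = 0.1)) {
    bd <- heterotroph_budget("NO2->NH4", fs)
    b1 <- heterotroph_budget("NO2->N2O", fs)
    expect_equal((bd$om / bd$no2) / (b1$om / b1$no2), 3, tolerance = 1e-10)
  }
  expect_error(consumption_vector(nf_comm$types$anammox), "no organic matter")
})

test_that("trait-table anammox subsistence concentration is recovered", {
  # with the trait-table nitrite yield, shared kinetics reproduce the
  # reported anammox NO2* of 0.0123 uM
  c2 <- community(anammox_y_n = 0.0133)
  expect_equal(
    unname(subsistence_concentration(c2$types$anammox, "no2")),
    0.0123, tolerance = 1e-2)
  expect_lt(abs(subsistence_concentration(c2$types$anammox, "no2") - 0.0123),
            1e-4)
})

test_that("community assembly validates persistence and subsetting", {
  expect_named(nf_comm$types, c("dnra", "denit1", "denit2", "anammox"))
  sub <- community_subset(nf_comm, "dnra")
  expect_named(sub$types, "dnra")
  expect_error(community_subset(nf_comm, "nitrifier"))
  # a type that can never persist is rejected
  b <- heterotroph_budget("NO2->NH4", 0.1)
  expect_error(functional_type(b, kinetics = list(v_max = 1, k = c(om = 1, no2 = 1)),
                               d = 0.5), "never persist")
  expect_s3_class(tidy(nf_comm), "tbl_df")
})
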