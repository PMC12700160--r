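test_that("electron equivalents follow half-reaction bookkeeping", {
  expect_equal(electron_equivalents("C5H7O2N"), 20)
  expect_equal(electron_equivalents("C6.6H10.9O2.6N"), 29.1)
  expect_equal(electron_equivalents("CH2O"), 4)
  expect_error(electron_equivalents("CO2"), "non-positive")
  expect_error(parse_chemical_formula("C6Xe2"), "cannot parse")
  f <- parse_chemical_formula("C6.6H10.9O2.6N")
  expect_equal(unclass(f), c(c = 6.6, h = 10.9, o = 2.6, n = 1),
               ignore_attr = TRUE)
})

test_that("synthesis-fraction calibration inverts the OM yield and round-trips", {
  expect_equal(calibrate_fs(1 / 6.8), 20 / (6.8 * 29.1))
  expect_equal(calibrate_fs(0.24), 20 * 0.24 / 29.1)
  expect_error(calibrate_fs(0), "strictly between")
  expect_error(calibrate_fs(29.1 / 20), "strictly between")
  # round trip: a budget built from the calibrated fs returns the target yield
  for (target in c(0.1, 1 / 6.8, 0.24, 0.4)) {
    b <- heterotroph_budget("NO2->NH4", calibrate_fs(target))
    expect_equal(b$y_om, target, tolerance = 1e-12)
  }
  # fs -> 1 limit: no respiration electrons, acceptor consumption vanishes
  b1 <- heterotroph_budget("NO2->N2O", 1 - 1e-9)
  expect_lt(-b1$no2, 1e-6)
})

test_that("midpoint budgets reproduce the reference equation coefficients", {
  b <- metabolic_budgets(y_base = 0.25)
  dnra <- b[b$metabolism == "dnra", ]
  expect_equal(round_half_up(-dnra$om), 6.8)
  expect_equal(round_half_up(-dnra$no2), 29.7)
  expect_equal(round_half_up(dnra$nh4), 35.5)
  expect_equal(round_half_up(dnra$dic), 39.9)
  den <- b[b$metabolism == "denit1", ]
  # the unrounded OM coefficient follows from the DIC coefficient by C balance
  expect_equal(-den$om, 27.5 / 6.6, tolerance = 1e-12)
  expect_equal(round_half_up(-den$no2), 50.6)
  expect_equal(round_half_up(den$n2o_n), 50.6)  # N2O reported in mol N
  expect_equal(round_half_up(den$nh4), 3.2)
  expect_equal(round_half_up(den$dic), 22.5)
  res <- budget_balances(b)
  expect_true(all(abs(res$n_residual) < 1e-9))
  expect_true(all(abs(res$c_residual) < 1e-9))
  expect_true(all(abs(res$e_residual) < 1e-9, na.rm = TRUE))
})

test_that("anammox budget closes nitrogen exactly at any yield", {
  a <- anammox_budget()
  expect_equal(-a$no2, 80.7)
  expect_equal(-a$nh4, 70.4)
  expect_equal(-a$dic, 5)
  expect_equal(a$no3, 11.3)
  # N2 recovered from N balance of the other printed coefficients (mol N2)
  expect_equal(a$n2_n / 2, (80.7 + 70.4 - 1 - 11.3) / 2)
  expect_equal(a$n2_n / 2, 69.4)
  # total N on each side
  expect_equal(80.7 + 70.4, 1 + a$n2_n + a$no3)
  expect_equal(a$y_n, 1 / 80.7)
  # trait-table override keeps the balance exact
  a2 <- anammox_budget(y_n = 0.0133)
  expect_equal(-a2$no2, 1 / 0.0133)
  expect_equal(-a2$no2 - a2$nh4, 1 + a2$n2_n + a2$no3, tolerance = 1e-12)
  expect_error(anammox_budget(y_n = 0.01, catabolic_scale = 2), "at most one")
})

test_that("random heterotroph budgets balance N, C and electrons", {
  set.seed(421)
  accs <- acceptor_half_reactions()$acceptor
  for (i in 1:25) {
    fs <- runif(1, 0.01, 0.9)
    f <- elemental_formula(runif(1, 2, 8), runif(1, 6, 14), runif(1, 0, 2),
                           runif(1, 0.5, 1.5))
    acc <- sample(accs, 1)
    b <- heterotroph_budget(acc, fs, om_formula = f)
    res <- budget_balances(b, om_formula = f)
    expect_lt(abs(res$n_residual), 1e-9)
    expect_lt(abs(res$c_residual), 1e-9)
    expect_lt(abs(res$e_residual), 1e-9)
  }
})

test_that("yields and the OM:acceptor ratio increase strictly with fs", {
  fs_grid <- seq(0.05, 0.9, by = 0.05)
  b <- purrr::map_dfr(fs_grid, ~heterotroph_budget("NO2->NH4", .x))
  expect_true(all(diff(b$y_om) > 0))
  expect_true(all(diff(b$y_n) > 0))
  expect_true(all(diff(b$om / b$no2) > 0))  # consumption ratio om/acceptor
})

test_that("baseline scaling reproduces the trait-table yield ranges", {
  lo <- metabolic_budgets(y_base = 0.2)
  hi <- metabolic_budgets(y_base = 0.3)
  tol <- 1e-3
  rng <- function(tbl, met, col) tbl[[col]][tbl$metabolism == met]
  expect_gte(rng(lo, "dnra", "y_om"), 0.11 - tol)
  expect_lte(rng(hi, "dnra", "y_om"), 0.18 + tol)
  expect_gte(rng(lo, "dnra", "y_n"), 0.026 - tol)
  expect_lte(rng(hi, "dnra", "y_n"), 0.042 + tol)
  expect_gte(rng(lo, "denit1", "y_om"), 0.19 - tol)
  expect_lte(rng(hi, "denit1", "y_om"), 0.29 + tol)
  expect_gte(rng(lo, "denit1", "y_n"), 0.015 - tol)
  expect_lte(rng(hi, "denit1", "y_n"), 0.024 + tol)
  expect_error(metabolic_budgets(y_base = 0.35), "0.2, 0.3")
})
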