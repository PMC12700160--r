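#' Single-step acceptor half reactions
#'
#' The modelled heterotrophic metabolisms each respire onto a single
#' nitrogen-cycle half reaction. Electrons accepted per mole of N processed:
#' NO3- to NO2- and NO2- to N2O accept 2, NO2- to NH4+ accepts 6, and N2O to
#' N2 accepts 1 per N. Anammox is chemoautotrophic and handled separately by
#' [anammox_budget()].
#'
#' @return A tibble with one row per half reaction: `acceptor` (label),
#'   `consumed_pool`, `product_pool` (dissolved-pool names used throughout the
#'   package), and `electrons_per_mol_n`.
#' @export
acceptor_half_reactions <- function() {
  tibble::tibble(
    acceptor = c("NO3->NO2", "NO2->NH4", "NO2->N2O", "N2O->N2"),
    consumed_pool = c("no3", "no2", "no2", "n2o_n"),
    product_pool = c("no2", "nh4", "n2o_n", "n2_n"),
    electrons_per_mol_n = c(2, 6, 2, 1)
  )
}

#' Calibrate the synthesis-electron fraction from a target OM yield
#'
#' The fraction `fs` of electron-donor equivalents routed to biomass synthesis
#' fixes the OM yield through `y_OM = fs * eeq_OM / eeq_B` (mol biomass N per
#' mol OM, with `eeq_B` the biomass electron equivalents per mol biomass N).
#' This inverts that relation so budgets can be anchored to empirically
#' estimated yields.
#'
#' @param target_y_om Target yield, mol biomass N per mol OM; must lie in
#'   `(0, eeq_OM / eeq_B)`.
#' @param om_formula Organic-matter composition (string or
#'   [elemental_formula()]).
#' @param biomass Biomass composition.
#' @return The synthesis fraction `fs` (scalar in (0, 1)).
#' @export
calibrate_fs <- function(target_y_om, om_formula = marine_om_formula(),
                         biomass = biomass_formula()) {
  om <- as_elemental_formula(om_formula)
  bio <- as_elemental_formula(biomass)
  eeq_om <- electron_equivalents(om)
  eeq_b <- electron_equivalents(bio) / bio[["n"]]
  upper <- eeq_om / eeq_b
  if (!is.numeric(target_y_om) || target_y_om <= 0 || target_y_om >= upper) {
    stop("target_y_om must lie strictly between 0 and eeq_OM/eeq_B = ",
         format(upper), call. = FALSE)
  }
  eeq_b * target_y_om / eeq_om
}

#' Build a mass-, N-, C- and electron-balanced heterotroph budget
#'
#' Generates the stoichiometric budget of a heterotrophic metabolism,
#' normalized to the synthesis of one mole of biomass nitrogen. Per mol
#' biomass N, with synthesis fraction `fs` and `e` electrons accepted per mol
#' acceptor N:
#' \deqn{OM = eeq_B/(f_s\,eeq_{OM}), \quad
#'       Acc = eeq_B (1-f_s)/(f_s\, e)}
#' Ammonium release is the organic N liberated in excess of biomass synthesis
#' (plus the reduced acceptor N for nitrite ammonification), and DIC release
#' closes the carbon balance.
#'
#' @param acceptor One of the half-reaction labels in
#'   [acceptor_half_reactions()].
#' @param fs Synthesis-electron fraction in (0, 1).
#' @param om_formula,biomass Compositions of the organic-matter pool and of
#'   biomass.
#' @param metabolism Optional label; defaults to the acceptor label.
#' @return A one-row tibble with columns `metabolism`, `acceptor`, `fs`,
#'   `electrons_per_mol_n`, the signed net coefficients `om`, `no2`, `nh4`,
#'   `n2o_n`, `n2_n`, `no3`, `dic` (mol per mol biomass N; negative =
#'   consumed; N2O and N2 expressed in mol N), and the yields `y_om`, `y_n`
#'   (biomass N per mol OM / per mol acceptor N).
#' @examples
#' # nitrite ammonification (DNRA) at its midpoint calibration
#' heterotroph_budget("NO2->NH4", fs_midpoint_anchors()[["dnra"]])
#' @export
heterotroph_budget <- function(acceptor, fs, om_formula = marine_om_formula(),
                               biomass = biomass_formula(), metabolism = NULL) {
  half <- acceptor_half_reactions()
  if (!acceptor %in% half$acceptor) {
    stop("unknown acceptor '", acceptor, "'; see acceptor_half_reactions()",
         call. = FALSE)
  }
  if (!is.numeric(fs) || fs <= 0 || fs >= 1) {
    stop("fs must lie strictly in (0, 1)", call. = FALSE)
  }
  half <- half[half$acceptor == acceptor, ]
  om <- as_elemental_formula(om_formula)
  bio <- as_elemental_formula(biomass)
  eeq_om <- electron_equivalents(om)
  # normalize biomass to one mole of biomass N
  eeq_b <- electron_equivalents(bio) / bio[["n"]]
  c_b <- bio[["c"]] / bio[["n"]]

  om_cons <- eeq_b / (fs * eeq_om)
  acc_cons <- eeq_b * (1 - fs) / (fs * half$electrons_per_mol_n)

  coef <- c(om = 0, no2 = 0, nh4 = 0, n2o_n = 0, n2_n = 0, no3 = 0, dic = 0)
  coef[["om"]] <- -om_cons
  coef[[half$consumed_pool]] <- coef[[half$consumed_pool]] - acc_cons
  coef[[half$product_pool]] <- coef[[half$product_pool]] + acc_cons
  # organic N not fixed into biomass is released as ammonium
  coef[["nh4"]] <- coef[["nh4"]] + om_cons * om[["n"]] - 1
  coef[["dic"]] <- om_cons * om[["c"]] - c_b

  tibble::tibble(
    metabolism = metabolism %||% acceptor,
    acceptor = acceptor,
    fs = fs,
    electrons_per_mol_n = half$electrons_per_mol_n,
    !!!coef,
    y_om = 1 / om_cons,
    y_n = 1 / acc_cons
  )
}

#' The chemoautotrophic anammox budget
#'
#' Anammox couples ammonium oxidation to nitrite reduction (1:1 to N2) and
#' oxidizes additional nitrite to nitrate to supply electrons for carbon
#' fixation. The default parameterization is the measured budget, per mol
#' biomass N: 80.7 NO2- + 70.4 NH4+ + 5 DIC consumed; 69.4 N2 (138.8 mol N)
#' and 11.3 NO3- produced. The budget decomposes into a fixed anabolic part
#' (1 NH4+ into biomass, 5 DIC, 11.3 NO2- oxidized to NO3-) and a 1:1
#' catabolic part (69.4 NO2- + 69.4 NH4+ -> 69.4 N2); yield overrides rescale
#' only the catabolic part, so nitrogen balance is exact for any yield.
#'
#' @param y_n Optional nitrite yield override (mol biomass N per mol NO2-),
#'   e.g. 0.0133 to use the trait-table value instead of the budget value
#'   1/80.7.
#' @param catabolic_scale Optional direct scale factor on the catabolic part
#'   (1 = measured budget). Supply at most one of `y_n`, `catabolic_scale`.
#' @return A one-row tibble in the same layout as [heterotroph_budget()]
#'   (`y_om` is `NA`: anammox consumes no organic matter).
#' @export
anammox_budget <- function(y_n = NULL, catabolic_scale = NULL) {
  if (!is.null(y_n) && !is.null(catabolic_scale)) {
    stop("supply at most one of y_n and catabolic_scale", call. = FALSE)
  }
  cat_n2 <- 69.4   # mol NO2- (and mol NH4+) to N2 per mol biomass N, measured
  ana_no3 <- 11.3  # mol NO2- oxidized to NO3- for carbon fixation
  scale <- 1
  if (!is.null(y_n)) {
    scale <- (1 / y_n - ana_no3) / cat_n2
    if (!is.finite(scale) || scale <= 0) {
      stop("y_n override must be below 1/", ana_no3, call. = FALSE)
    }
  } else if (!is.null(catabolic_scale)) {
    stopifnot(catabolic_scale > 0)
    scale <- catabolic_scale
  }
  no2_cons <- cat_n2 * scale + ana_no3
  nh4_cons <- cat_n2 * scale + 1
  tibble::tibble(
    metabolism = "anammox",
    acceptor = "anammox",
    fs = NA_real_,
    electrons_per_mol_n = NA_real_,
    om = 0,
    no2 = -no2_cons,
    nh4 = -nh4_cons,
    n2o_n = 0,
    n2_n = 2 * cat_n2 * scale,
    no3 = ana_no3,
    dic = -5,
    y_om = NA_real_,
    y_n = 1 / no2_cons
  )
}

#' Midpoint synthesis-fraction anchors
#'
#' The synthesis fractions that reproduce the reference budgets of the two
#' nitrite-reducing heterotrophs at the midpoint (0.25 mol/mol) of the
#' empirical 0.2--0.3 baseline carbon-use-efficiency range. The nitrite
#' ammonification (DNRA) anchor solves the unrounded OM coefficient `x` from
#' the reference ammonium coefficient 35.5 via nitrogen balance,
#' `x - 1 + (eeq_OM x - eeq_B)/6 = 35.5`; the denitrification (NO2- to N2O)
#' anchor infers its OM coefficient from the reference DIC coefficient 22.5
#' via carbon balance, `x = (22.5 + 5)/c_OM`. Both anchors are defined for
#' the marine organic-matter composition.
#'
#' @return Named numeric vector `c(dnra = ..., denit = ...)`.
#' @export
fs_midpoint_anchors <- function() {
  om <- marine_om_formula()
  bio <- biomass_formula()
  eeq_om <- electron_equivalents(om)
  eeq_b <- electron_equivalents(bio) / bio[["n"]]
  c_b <- bio[["c"]] / bio[["n"]]
  # DNRA: nh4 = x*n_om - 1 + (eeq_om*x - eeq_b)/6 = 35.5
  x_dnra <- (35.5 + 1 + eeq_b / 6) / (om[["n"]] + eeq_om / 6)
  # denitrification step 1: dic = x*c_om - c_b = 22.5
  x_den <- (22.5 + c_b) / om[["c"]]
  c(dnra = eeq_b / (x_dnra * eeq_om), denit = eeq_b / (x_den * eeq_om))
}

#' Synthesis fractions at a baseline carbon-use efficiency
#'
#' Per-metabolism synthesis fractions scale linearly with the baseline
#' carbon-use efficiency `y_base` (mol biomass C per mol organic C), anchored
#' at the midpoint values of [fs_midpoint_anchors()]:
#' `fs_i(y_base) = fs_i(0.25) * y_base / 0.25`.
#'
#' @param y_base Baseline carbon-use efficiency in \[0.2, 0.3\].
#' @return Named numeric vector `c(dnra = ..., denit = ...)`.
#' @export
fs_at_baseline <- function(y_base = 0.25) {
  if (!is.numeric(y_base) || y_base < 0.2 || y_base > 0.3) {
    stop("y_base must lie in [0.2, 0.3]", call. = FALSE)
  }
  fs_midpoint_anchors() * y_base / 0.25
}

#' Metabolic budgets of the modelled community
#'
#' Generates the budgets of all four functional types (nitrite
#' ammonification/DNRA, the two single-step denitrification populations, and
#' anammox) at a given baseline carbon-use efficiency.
#'
#' @param y_base Baseline carbon-use efficiency in \[0.2, 0.3\] (midpoint
#'   0.25 reproduces the reference budget coefficients).
#' @param om_formula Organic-matter composition.
#' @param include_anammox Include the anammox row? (default `TRUE`).
#' @param anammox_y_n Optional anammox nitrite-yield override, passed to
#'   [anammox_budget()].
#' @param fs_denit2 Synthesis fraction for the N2O-reducing step; defaults to
#'   1.1 times the NO2- to N2O step's value. The N2O/N2 couple is the most
#'   exergonic denitrification step per electron, so its synthesis fraction
#'   is taken strictly higher; a strictly higher OM yield is also required
#'   for the second step to persist stably as the pathway's N2O scavenger
#'   (with exactly equal OM yields the two steps share one OM subsistence
#'   concentration and the coexistence equilibrium degenerates into a
#'   neutral family of states that vent N2O). Steady-state community fluxes
#'   are insensitive to the exact increment.
#' @return A tibble, one row per metabolism, in the layout of
#'   [heterotroph_budget()]. Coefficients are signed net productions per mol
#'   biomass N (negative = consumed).
#' @examples
#' metabolic_budgets()            # midpoint budgets
#' metabolic_budgets(y_base = 0.2)
#' @export
metabolic_budgets <- function(y_base = 0.25, om_formula = marine_om_formula(),
                              include_anammox = TRUE, anammox_y_n = NULL,
                              fs_denit2 = NULL) {
  fs <- fs_at_baseline(y_base)
  out <- dplyr::bind_rows(
    heterotroph_budget("NO2->NH4", fs[["dnra"]], om_formula, metabolism = "dnra"),
    heterotroph_budget("NO2->N2O", fs[["denit"]], om_formula, metabolism = "denit1"),
    heterotroph_budget("N2O->N2", fs_denit2 %||% (1.1 * fs[["denit"]]),
                       om_formula, metabolism = "denit2")
  )
  if (include_anammox) out <- dplyr::bind_rows(out, anammox_budget(y_n = anammox_y_n))
  out
}

#' Elemental balance residuals of a budget table
#'
#' Verifies that each budget conserves nitrogen, carbon, and (for
#' heterotrophs) donor electrons. All residuals are zero to numerical
#' precision for budgets generated by this package.
#'
#' @param budgets A budget tibble from [metabolic_budgets()],
#'   [heterotroph_budget()] or [anammox_budget()].
#' @param om_formula,biomass Compositions used to build the budgets.
#' @return A tibble with `metabolism`, `n_residual`, `c_residual`,
#'   `e_residual` (mol per mol biomass N; `e_residual` is `NA` for anammox).
#' @export
budget_balances <- function(budgets, om_formula = marine_om_formula(),
                            biomass = biomass_formula()) {
  om <- as_elemental_formula(om_formula)
  bio <- as_elemental_formula(biomass)
  eeq_om <- electron_equivalents(om)
  eeq_b <- electron_equivalents(bio) / bio[["n"]]
  c_b <- bio[["c"]] / bio[["n"]]
  half <- acceptor_half_reactions()
  purrr::map_dfr(seq_len(nrow(budgets)), function(i) {
    row <- budgets[i, ]
    n_res <- row$om * om[["n"]] + row$no2 + row$nh4 + row$n2o_n + row$n2_n +
      row$no3 + 1
    c_res <- row$om * om[["c"]] + row$dic + c_b
    e_res <- NA_real_
    if (row$acceptor %in% half$acceptor) {
      acc_pool <- half$consumed_pool[half$acceptor == row$acceptor]
      acc_cons <- -row[[acc_pool]]
      # donor electrons = biomass electrons + respired electrons
      e_res <- -row$om * eeq_om - eeq_b - acc_cons * row$electrons_per_mol_n
    }
    tibble::tibble(metabolism = row$metabolism, n_residual = n_res,
                   c_residual = c_res, e_residual = e_res)
  })
}

#' Round as printed (one decimal, half up)
#'
#' Display rounding used for budget coefficients; internal arithmetic never
#' rounds.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 1).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
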