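#' Classify the competitive regime of a steady state
#'
#' Labels the surviving community and flags "accumulating" nutrients: a
#' resource accumulates when its steady concentration exceeds the
#' subsistence concentration of every surviving consumer of that resource
#' (or any positive concentration, if no surviving type consumes it). The
#' label predicted from consumption-vector geometry (the supply ratio
#' relative to the nitrite-ammonifier CV and the full-pathway
#' denitrification CV) is attached as a cross-check.
#'
#' @param record An [steady_state()] result (must be converged).
#' @param comm The [community()] that produced it.
#' @return A one-row tibble: `regime`, `predicted_regime` (CV geometry,
#'   heterotrophs only), and logical accumulation flags `om_accumulates`,
#'   `no2_accumulates`, `nh4_accumulates`.
#' @export
classify_regime <- function(record, comm) {
  if (!record$converged) {
    stop("cannot classify a non-converged record", call. = FALSE)
  }
  B <- record$biomass
  alive <- names(B)[B > 0]
  het <- intersect(alive, c("dnra", "denit1", "denit2"))
  has_dnra <- "dnra" %in% alive
  has_den <- any(c("denit1", "denit2") %in% alive)
  has_amx <- "anammox" %in% alive
  regime <- if (!length(alive)) "washout"
  else if (has_dnra && has_den && has_amx) "all-three"
  else if (has_dnra && has_den) "denit+DNRA coexistence"
  else if (has_den && has_amx) "denit+anammox"
  else if (has_dnra && has_amx) "DNRA+anammox"
  else if (has_den) "denit-only"
  else if (has_dnra) "DNRA-only"
  else "anammox-only"

  # a pool pinned by a surviving consumer sits exactly at that consumer's
  # R*; a small relative margin keeps the flag off there
  accumulates <- function(pool, margin = 1e-3) {
    conc <- record$pools[[pool]]
    consumers <- purrr::keep(comm$types, function(ft) {
      ft$label %in% alive && pool %in% ft$required
    })
    if (!length(consumers)) return(conc > sqrt(.Machine$double.eps))
    all(purrr::map_lgl(consumers, function(ft) {
      conc > subsistence_concentration(ft, pool) * (1 + margin)
    }))
  }

  tibble::tibble(
    regime = regime,
    predicted_regime = predict_regime_cv(
      record$config$om_in, record$config$no2_in, comm),
    om_accumulates = accumulates("om"),
    no2_accumulates = accumulates("no2"),
    nh4_accumulates = accumulates("nh4")
  )
}

#' Realized full-pathway denitrification consumption vector
#'
#' The organic matter consumed per mole of nitrite fully reduced to N2 by
#' the two-step pathway, computed from the community's actual budgets:
#' `|om1|/|no2_1| + |om2|/|n2o_2|` (each mole of NO2- reduced by step 1
#' yields one mole of N2O-N for step 2).
#'
#' @param comm An [community()] containing `denit1` and `denit2`.
#' @return The pathway consumption vector (mol OM per mol NO2-).
#' @export
pathway_cv <- function(comm) {
  b1 <- comm$types$denit1$budget
  b2 <- comm$types$denit2$budget
  unname(-b1$om / -b1$no2 + -b2$om / -b2$n2o_n)
}

#' Predict the heterotroph regime from consumption-vector geometry
#'
#' Resource-competition theory: denitrification excludes nitrite
#' ammonification at supply ratios `rho = OM_in/NO2_in` below its
#' (full-pathway) consumption vector; DNRA excludes denitrification above
#' its own CV; between the two CVs the heterotrophs stably coexist,
#' co-limited by both resources.
#'
#' @param om_in,no2_in Supply concentrations (uM N).
#' @param comm An [community()].
#' @return One of `"denit"`, `"coexist"`, `"dnra"`.
#' @export
predict_regime_cv <- function(om_in, no2_in, comm) {
  rho <- om_in / no2_in
  cv_den <- pathway_cv(comm)
  cv_dnra <- consumption_vector(comm$types$dnra)
  if (rho < cv_den) "denit" else if (rho > cv_dnra) "dnra" else "coexist"
}

#' Partition the fate of nitrite at steady state
#'
#' Fractions of the steady-state nitrite consumption flux routed through
#' nitrite ammonification, denitrification (step 1) and anammox, together
#' with the gross ammonium-regeneration and N2 production fluxes and the net
#' nitrogen loss.
#'
#' @param record An [steady_state()] result.
#' @return A one-row tibble: `no2_flux_total` (uM N per day), fate fractions
#'   `f_dnra`, `f_denit`, `f_anammox` (sum to 1 when consumption is active,
#'   otherwise all zero and `active = FALSE`), `nh4_production`,
#'   `nh4_production_dnra`, `n2_production`, `n2_production_anammox`, and
#'   `net_n_loss = n2_production - nh4_production_dnra`.
#' @export
nitrite_fate <- function(record) {
  fx <- record$fluxes
  cons <- function(met) {
    f <- fx$flux[fx$metabolism == met & fx$pool == "no2"]
    max(0, -f)
  }
  uptake <- c(dnra = cons("dnra"), denit = cons("denit1"),
              anammox = cons("anammox"))
  total <- sum(uptake)
  frac <- if (total > 0) uptake / total else uptake * 0
  prod <- function(met, pool) {
    f <- fx$flux[fx$metabolism == met & fx$pool == pool]
    if (length(f)) max(0, f) else 0
  }
  nh4_all <- sum(purrr::map_dbl(unique(fx$metabolism), prod, pool = "nh4"))
  n2_all <- sum(purrr::map_dbl(unique(fx$metabolism), prod, pool = "n2_n"))
  nh4_dnra <- prod("dnra", "nh4")
  n2_amx <- prod("anammox", "n2_n")
  tibble::tibble(
    no2_flux_total = total,
    f_dnra = frac[["dnra"]], f_denit = frac[["denit"]],
    f_anammox = frac[["anammox"]],
    active = total > 0,
    nh4_production = nh4_all, nh4_production_dnra = nh4_dnra,
    n2_production = n2_all, n2_production_anammox = n2_amx,
    net_n_loss = n2_all - nh4_dnra
  )
}

run_point <- function(comm, om_in, no2_in, ...) {
  ss <- steady_state(comm, om_in = om_in, no2_in = no2_in, ...)
  row <- glance(ss)
  row$rho <- om_in / no2_in
  if (ss$converged) {
    row <- dplyr::bind_cols(row, classify_regime(ss, comm), nitrite_fate(ss))
  }
  row
}

#' Steady states across a supply grid
#'
#' Runs one independent chemostat integration per supply point and collects
#' the steady states, regime labels and nitrite fate into a tibble
#' (row-major over the grid: `no2_in` varies fastest). Non-converged points
#' are flagged and the sweep continues.
#'
#' @param comm An [community()].
#' @param om_in,no2_in Numeric vectors spanning the grid (uM N).
#' @param ... Passed to [chemostat_config()].
#' @return A tibble of class `nf_sweep`, one row per grid point.
#' @export
supply_sweep <- function(comm, om_in, no2_in, ...) {
  stopifnot(length(om_in) > 0, length(no2_in) > 0)
  grid <- tidyr::expand_grid(om_in = om_in, no2_in = no2_in)
  out <- purrr::pmap_dfr(grid, function(om_in, no2_in) {
    run_point(comm, om_in, no2_in, ...)
  })
  class(out) <- c("nf_sweep", class(out))
  attr(out, "cv_lines") <- c(
    denit_full = pathway_cv(comm),
    dnra = consumption_vector(comm$types$dnra)
  )
  out
}

#' Transect at fixed nitrite supply
#'
#' A one-dimensional cut through supply space: fixed incoming nitrite
#' (default 25 uM N) and an increasing organic-matter supply sequence.
#'
#' @param comm An [community()].
#' @param om_in Increasing sequence of OM supplies (uM N).
#' @param no2_in Incoming nitrite (uM N).
#' @param ... Passed to [chemostat_config()].
#' @return A tibble of class `nf_transect`, ordered by `om_in`, with the
#'   same columns as [supply_sweep()].
#' @export
transect <- function(comm, om_in = seq(0.25, 8, by = 0.25), no2_in = 25,
                     ...) {
  if (is.unsorted(om_in, strictly = TRUE)) {
    stop("om_in must be strictly increasing", call. = FALSE)
  }
  out <- purrr::map_dfr(om_in, function(o) run_point(comm, o, no2_in, ...))
  class(out) <- c("nf_transect", class(out))
  attr(out, "cv_lines") <- c(
    denit_full = pathway_cv(comm),
    dnra = consumption_vector(comm$types$dnra)
  )
  out
}

#' Analytic net-zero-nitrogen-loss supply ratio
#'
#' The OM:NO2- supply ratio at which ammonium regeneration by nitrite
#' ammonification balances N2 production, assuming equal steady-state growth
#' rates, is the arithmetic mean of the two heterotroph consumption vectors:
#' \deqn{\rho_0 = \tfrac12 (cv_{denit} + cv_{DNRA})}
#' Mode `"full-pathway"` (default) charges the denitrification CV with the
#' organic matter consumed across both steps (3 respired electrons per N);
#' mode `"step1"` uses only the NO2- to N2O step's yields.
#'
#' @param y_base Baseline carbon-use efficiency in \[0.2, 0.3\].
#' @param mode `"full-pathway"` or `"step1"`.
#' @param om_formula Organic-matter composition.
#' @return The supply ratio (mol N in OM per mol NO2- supplied).
#' @examples
#' net_zero_analytic(0.25)
#' net_zero_analytic(0.2); net_zero_analytic(0.3)  # the baseline interval
#' @export
net_zero_analytic <- function(y_base = 0.25,
                              mode = c("full-pathway", "step1"),
                              om_formula = marine_om_formula()) {
  mode <- match.arg(mode)
  fs <- fs_at_baseline(y_base)
  eeq_om <- electron_equivalents(om_formula)
  cv_dnra <- 6 / (eeq_om * (1 - fs[["dnra"]]))
  cv_den <- if (mode == "full-pathway") {
    3 / (eeq_om * (1 - fs[["denit"]]))
  } else {
    2 / (eeq_om * (1 - fs[["denit"]]))
  }
  unname((cv_dnra + cv_den) / 2)
}

#' Numerical net-zero balance point
#'
#' Locates, by root bracketing on the OM supply at fixed incoming nitrite,
#' the supply ratio at which the chosen balance holds at steady state:
#' * `"no2-flux"` (default): nitrite reduction by the nitrite ammonifier
#'   equals nitrite reduction by the denitrification pathway (the
#'   equal-reduction balance implied by equal growth rates);
#' * `"nh4-vs-n2"`: total gross ammonium production equals total N2-N
#'   production.
#'
#' A coarse scan of the search interval brackets a sign change, refined by
#' [stats::uniroot()] to `tol` in the supply ratio.
#'
#' @param comm An [community()].
#' @param no2_in Incoming nitrite (uM N).
#' @param balance Balance definition (see above).
#' @param interval Search interval for the supply ratio `rho`; default spans
#'   just beyond the heterotroph consumption vectors.
#' @param n_scan Number of coarse-scan points.
#' @param tol Bracketing tolerance in `rho`.
#' @param ... Passed to [chemostat_config()].
#' @return A list: `rho`, `om_in`, `balance`, and the steady-state `record`
#'   at the balance point.
#' @export
net_zero_numeric <- function(comm, no2_in = 25,
                             balance = c("no2-flux", "nh4-vs-n2"),
                             interval = NULL, n_scan = 13, tol = 1e-4, ...) {
  balance <- match.arg(balance)
  if (is.null(interval)) {
    cv_den <- pathway_cv(comm)
    cv_dnra <- consumption_vector(comm$types$dnra)
    interval <- c(0.5 * cv_den, 1.1 * cv_dnra)
  }
  g <- function(rho) {
    ss <- steady_state(comm, om_in = rho * no2_in, no2_in = no2_in, ...)
    fate <- nitrite_fate(ss)
    if (balance == "no2-flux") {
      fate$no2_flux_total * (fate$f_dnra - fate$f_denit)
    } else {
      fate$nh4_production - fate$n2_production
    }
  }
  rho_grid <- seq(interval[1], interval[2], length.out = n_scan)
  vals <- purrr::map_dbl(rho_grid, g)
  sign_change <- which(vals[-1] * vals[-length(vals)] < 0)
  if (!length(sign_change)) {
    hit <- which(vals == 0)
    if (length(hit) && balance == "no2-flux") {
      # an exact zero only occurs when both fluxes vanish; not a balance
      hit <- integer(0)
    }
    if (length(hit)) {
      rho0 <- rho_grid[hit[1]]
    } else {
      stop("no sign change of the '", balance, "' balance in rho interval [",
           format(interval[1]), ", ", format(interval[2]), "]", call. = FALSE)
    }
  } else {
    i <- sign_change[1]
    rho0 <- uniroot(g, c(rho_grid[i], rho_grid[i + 1]), tol = tol)$root
  }
  record <- steady_state(comm, om_in = rho0 * no2_in, no2_in = no2_in, ...)
  list(rho = rho0, om_in = rho0 * no2_in, balance = balance, record = record)
}

#' Algebraic three-type coexistence equilibrium
#'
#' Solves the steady state in which all four populations (nitrite
#' ammonifier, both denitrification steps, anammox) persist simultaneously.
#' The limitation structure is fixed by the trait ordering: the nitrite
#' ammonifier is OM-limited (OM drawn to its OM*), denitrification step 1 is
#' nitrite-limited (NO2- at its R*), step 2 is N2O-limited, and anammox is
#' ammonium-limited. The four resource balances are then linear in the four
#' synthesis rates and solved directly. The equilibrium is reported with a
#' feasibility flag: it exists only where all synthesis rates are positive
#' and every population's non-limiting Monod terms exceed the loss rate.
#'
#' Note: where feasible this equilibrium is a true steady state of the
#' dynamics but is not necessarily dynamically stable; under the
#' superior-nitrite-competitor scenario it is unstable and acts as the
#' separatrix between the denitrification+anammox and DNRA+anammox states.
#'
#' @param comm An [community()] with all four types.
#' @param om_in,no2_in Supply concentrations (uM N).
#' @param nh4_in Ammonium supply (uM N); `NULL` uses
#'   `nh4_supply_ratio() * no2_in`.
#' @return A one-row tibble: supply point, the pinned resource
#'   concentrations, biomasses `b_*` (uM N), and `feasible`.
#' @export
three_type_equilibrium <- function(comm, om_in, no2_in, nh4_in = NULL) {
  d <- comm$d
  nh4_in <- nh4_in %||% (nh4_supply_ratio(comm$y_base) * no2_in)
  pin <- c(
    om = unname(subsistence_concentration(comm$types$dnra, "om")),
    no2 = unname(subsistence_concentration(comm$types$denit1, "no2")),
    n2o_n = unname(subsistence_concentration(comm$types$denit2, "n2o_n")),
    nh4 = unname(subsistence_concentration(comm$types$anammox, "nh4"))
  )
  inflow <- c(om = om_in, no2 = no2_in, n2o_n = 0, nh4 = nh4_in)
  pools <- names(pin)
  types <- nf_types()
  M <- sapply(pools, function(p) {
    sapply(types, function(tt) comm$types[[tt]]$budget[[p]])
  })  # types x pools, signed
  s <- tryCatch(solve(t(M), -d * (inflow - pin)), error = function(e) rep(NA_real_, 4))
  names(s) <- types
  conc <- c(pin, n2_n = 0, no3 = 0, dic = 0)
  consistent <- all(is.finite(s)) && all(s > 0) &&
    all(purrr::map_lgl(types, function(tt) {
      ft <- comm$types[[tt]]
      all(monod_terms(ft, conc) >= d - 1e-9)
    }))
  tibble::tibble(
    om_in = om_in, no2_in = no2_in, nh4_in = nh4_in,
    rho = om_in / no2_in,
    om = pin[["om"]], no2 = pin[["no2"]], n2o_n = pin[["n2o_n"]],
    nh4 = pin[["nh4"]],
    !!!setNames(as.list(unname(s) / d), paste0("b_", types)),
    feasible = isTRUE(consistent)
  )
}

#' @rdname three_type_equilibrium
#' @param rho Supply-ratio grid over which to map feasibility.
#' @return `three_type_window`: the subset of the grid (as a tibble) where
#'   the equilibrium is feasible.
#' @export
three_type_window <- function(comm, no2_in = 25,
                              rho = seq(0.02, 0.26, by = 0.005),
                              nh4_in = NULL) {
  out <- purrr::map_dfr(rho, function(r) {
    three_type_equilibrium(comm, om_in = r * no2_in, no2_in = no2_in,
                           nh4_in = nh4_in)
  })
  dplyr::filter(out, .data$feasible)
}

#' Anammox contribution to nitrite uptake and N2 production
#'
#' For a single steady state: the percentage of the nitrite consumption flux
#' taken by anammox and the percentage of N2-N production it contributes
#' (zero, with `active = FALSE`, when anammox is extinct or fluxes vanish).
#' For a transect: in addition to per-point shares, the flux-weighted shares
#' over the band where anammox persists (total anammox flux divided by total
#' flux, summed across those points) — the transect-level summary of the
#' anammox contribution in the organic-matter-limited regime.
#'
#' @param x An [steady_state()] record or an `nf_transect`.
#' @return For a record: one-row tibble `pct_no2_uptake`, `pct_n2_production`,
#'   `active`. For a transect: a list with `by_point` (tibble) and
#'   `aggregate` (one-row tibble with the flux-weighted percentages and the
#'   number of contributing points `n_points`).
#' @export
anammox_contribution <- function(x) {
  if (inherits(x, "nf_steady_state")) {
    fate <- nitrite_fate(x)
    active <- fate$active && fate$f_anammox > 0
    return(tibble::tibble(
      pct_no2_uptake = 100 * fate$f_anammox,
      pct_n2_production = if (fate$n2_production > 0) {
        100 * fate$n2_production_anammox / fate$n2_production
      } else 0,
      active = active
    ))
  }
  stopifnot(inherits(x, "nf_transect"))
  pts <- dplyr::filter(x, .data$converged, .data$b_anammox > 0)
  by_point <- dplyr::transmute(
    pts,
    om_in = .data$om_in, rho = .data$rho,
    pct_no2_uptake = 100 * .data$f_anammox,
    pct_n2_production = dplyr::if_else(
      .data$n2_production > 0,
      100 * .data$n2_production_anammox / .data$n2_production, 0)
  )
  amx_no2 <- sum(pts$no2_flux_total * pts$f_anammox)
  tot_no2 <- sum(pts$no2_flux_total)
  amx_n2 <- sum(pts$n2_production_anammox)
  tot_n2 <- sum(pts$n2_production)
  list(
    by_point = by_point,
    aggregate = tibble::tibble(
      pct_no2_uptake = 100 * amx_no2 / tot_no2,
      pct_n2_production = 100 * amx_n2 / tot_n2,
      n_points = nrow(pts)
    )
  )
}
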