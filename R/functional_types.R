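#' Solve shared uptake kinetics from two subsistence concentrations
#'
#' At loss rate `d`, a population with yield `y` and Monod uptake
#' (`v_max`, `K`) subsists at \eqn{R^* = K d / (y\,v_{max} - d)}. Given two
#' populations that share the same kinetics on one resource but differ in
#' yield, their two `R*` values determine `(v_max, K)` uniquely:
#' \deqn{v_{max} = d\,(R^*_b - R^*_a) / (R^*_b y_b - R^*_a y_a)}
#'
#' @param y Numeric length-2: the two yields (mol biomass N per mol resource).
#' @param rstar Numeric length-2: the corresponding subsistence
#'   concentrations (uM).
#' @param d Loss (dilution) rate, per day.
#' @return A list with `v_max` (per day, mol resource per mol biomass N) and
#'   `k` (uM). Errors if no positive solution exists.
#' @examples
#' calibrate_kinetics_from_rstar(y = c(0.034, 0.0195),
#'                               rstar = c(0.0043, 0.00775), d = 0.1)
#' @export
calibrate_kinetics_from_rstar <- function(y, rstar, d) {
  stopifnot(length(y) == 2L, length(rstar) == 2L, d > 0)
  denom <- rstar[2] * y[2] - rstar[1] * y[1]
  if (denom == 0) {
    stop("calibration infeasible: the two (y, R*) pairs are contradictory",
         call. = FALSE)
  }
  v_max <- d * (rstar[2] - rstar[1]) / denom
  k <- rstar[1] * (y[1] * v_max - d) / d
  if (!is.finite(v_max) || v_max <= 0 || k <= 0 ||
      any(y * v_max <= d)) {
    stop("calibration infeasible: no positive (v_max, K) satisfies both R* ",
         "anchors at d = ", d, call. = FALSE)
  }
  list(v_max = v_max, k = k)
}

#' Default shared uptake kinetics
#'
#' All functional types share one maximum uptake rate and per-resource
#' half-saturation constants, so that competitive differences arise from the
#' redox-informed yields alone. `v_max` and `K` for nitrite are solved from
#' the trait-table midpoint subsistence concentrations of the two
#' nitrite-reducing heterotrophs (0.0043 and 0.00775 uM) paired with the
#' midpoint budget yields; `K` for organic matter is anchored to the
#' nitrite-ammonifier midpoint OM* of 0.10 uM at the shared `v_max`. N2O and
#' ammonium reuse the nitrite half-saturation.
#'
#' @param d Dilution (loss) rate, per day.
#' @param rstar_no2 Length-2 nitrite R* anchors (DNRA, denitrification), uM.
#' @param rstar_om_dnra OM* anchor for the nitrite ammonifier, uM.
#' @return A list with `v_max` (shared, per day) and `k`: named half
#'   saturations (uM) for pools `om`, `no2`, `n2o_n`, `nh4`.
#' @export
default_kinetics <- function(d = 0.1, rstar_no2 = c(0.0043, 0.00775),
                             rstar_om_dnra = 0.10) {
  mid <- metabolic_budgets(y_base = 0.25, include_anammox = FALSE)
  y_no2 <- c(mid$y_n[mid$metabolism == "dnra"],
             mid$y_n[mid$metabolism == "denit1"])
  fit <- calibrate_kinetics_from_rstar(y_no2, rstar_no2, d)
  y_om_dnra <- mid$y_om[mid$metabolism == "dnra"]
  k_om <- rstar_om_dnra * (y_om_dnra * fit$v_max - d) / d
  list(
    v_max = fit$v_max,
    k = c(om = unname(k_om), no2 = fit$k, n2o_n = fit$k, nh4 = fit$k)
  )
}

#' Package a metabolic budget as a functional type
#'
#' A functional type couples a stoichiometric budget to uptake kinetics and a
#' loss rate. Yields on each required resource are the reciprocals of the
#' budget's consumption coefficients; DIC is tracked stoichiometrically but
#' never treated as a limiting resource (large background pool).
#'
#' @param budget A one-row budget tibble ([heterotroph_budget()] /
#'   [anammox_budget()]).
#' @param kinetics Shared kinetics from [default_kinetics()].
#' @param d Loss rate (chemostat dilution), per day.
#' @return An object of class `functional_type`: list with `label`, `budget`,
#'   `required` (resource pools, in canonical order), `yields` (named), and
#'   `kinetics`.
#' @export
functional_type <- function(budget, kinetics = default_kinetics(d), d = 0.1) {
  stopifnot(nrow(budget) == 1L)
  coef <- unlist(budget[nf_pools()])
  consumed <- names(coef)[coef < 0 & names(coef) != "dic"]
  required <- intersect(nf_resource_order(), consumed)
  yields <- setNames(-1 / coef[required], required)
  missing_k <- setdiff(required, names(kinetics$k))
  if (length(missing_k)) {
    stop("kinetics lack half-saturation constants for: ",
         paste(missing_k, collapse = ", "), call. = FALSE)
  }
  ft <- structure(list(
    label = budget$metabolism,
    budget = budget,
    required = required,
    yields = yields,
    kinetics = list(v_max = kinetics$v_max, k = kinetics$k[required]),
    d = d
  ), class = "functional_type")
  mu_max <- max(yields * kinetics$v_max)
  if (mu_max <= d) {
    stop("functional type '", ft$label, "' can never persist: max growth ",
         format(mu_max), " <= loss rate ", d, call. = FALSE)
  }
  ft
}

#' @export
print.functional_type <- function(x, ...) {
  cat("<functional_type> ", x$label, "\n  required: ",
      paste(x$required, collapse = ", "),
      "\n  yields: ", paste(names(x$yields), signif(x$yields, 4),
                            sep = "=", collapse = ", "),
      "\n  d = ", x$d, ", v_max = ", signif(x$kinetics$v_max, 5), "\n",
      sep = "")
  invisible(x)
}

#' Growth rate under Liebig's law of the minimum
#'
#' \deqn{\mu_i = \min_j \left( y_{ij} V^{max}_j \frac{R_j}{R_j + K_j} \right)}
#'
#' @param ft A [functional_type()].
#' @param concentrations Named numeric vector of resource concentrations
#'   (uM); must contain every required resource.
#' @return Growth rate (per day).
#' @export
growth_rate <- function(ft, concentrations) {
  min(monod_terms(ft, concentrations))
}

monod_terms <- function(ft, concentrations) {
  missing <- setdiff(ft$required, names(concentrations))
  if (length(missing)) {
    stop("missing required resource(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  r <- pmax(concentrations[ft$required], 0)
  ft$yields * ft$kinetics$v_max * r / (r + ft$kinetics$k)
}

#' Identify the limiting resource
#'
#' Returns the argmin of the Liebig growth law; ties break deterministically
#' by the canonical resource ordering OM, NO2-, N2O, NH4+.
#'
#' @inheritParams growth_rate
#' @return A resource label (character scalar).
#' @export
limiting_resource <- function(ft, concentrations) {
  terms <- monod_terms(ft, concentrations)
  ft$required[which.min(terms)]  # required is already in canonical order
}

#' Subsistence concentration R*
#'
#' The concentration of a resource at which growth on that resource exactly
#' balances the loss rate: \eqn{R^* = K d / (y V^{max} - d)}. The superior
#' competitor for a limiting resource is the type with the lowest R*.
#'
#' @param ft A [functional_type()].
#' @param resource Resource pool name (e.g. `"no2"`); defaults to all
#'   required resources.
#' @return Named numeric vector of R* values (uM). Errors if persistence on
#'   a requested resource is infeasible (`y v_max <= d`).
#' @export
subsistence_concentration <- function(ft, resource = ft$required) {
  stopifnot(all(resource %in% ft$required))
  y <- ft$yields[resource]
  k <- ft$kinetics$k[resource]
  mu_max <- y * ft$kinetics$v_max
  if (any(mu_max <= ft$d)) {
    bad <- resource[mu_max <= ft$d]
    stop("R* undefined for '", paste(bad, collapse = ", "),
         "': maximum growth does not exceed the loss rate", call. = FALSE)
  }
  k * ft$d / (mu_max - ft$d)
}

#' Consumption vector of a heterotroph
#'
#' The ratio of organic-matter to nitrite consumption, `cv = y_N / y_OM`
#' (equivalently OM coefficient / acceptor coefficient). In resource-ratio
#' space the consumption vectors of the two nitrite-reducing heterotrophs
#' bound the coexistence region. For the denitrification pathway, mode
#' `"full"` charges the OM consumed by both steps against each mole of
#' nitrite fully reduced to N2 (3 respired electrons per N), giving
#' `cv = 3 / (eeq_OM (1 - fs))`.
#'
#' @param ft A [functional_type()] for a heterotroph.
#' @param mode `"step"` (the type's own budget; default) or `"full"` (whole
#'   two-step denitrification pathway; only meaningful for `denit1`).
#' @param om_formula Organic-matter composition (used for `mode = "full"`).
#' @return The consumption vector (dimensionless, mol OM per mol NO2-).
#' @export
consumption_vector <- function(ft, mode = c("step", "full"),
                               om_formula = marine_om_formula()) {
  mode <- match.arg(mode)
  if (is.na(ft$budget$y_om)) {
    stop("consumption vector undefined: '", ft$label,
         "' consumes no organic matter", call. = FALSE)
  }
  if (mode == "full") {
    eeq_om <- electron_equivalents(om_formula)
    return(3 / (eeq_om * (1 - ft$budget$fs)))
  }
  unname(ft$budget$y_n / ft$budget$y_om)
}

#' Assemble the default four-type community
#'
#' Builds the nitrite ammonifier (DNRA), the two single-step denitrifiers,
#' and anammox, sharing uptake kinetics and loss rate, from budgets at a
#' given baseline carbon-use efficiency.
#'
#' @inheritParams metabolic_budgets
#' @param d Dilution (loss) rate, per day.
#' @param kinetics Shared kinetics; default [default_kinetics()] at `d`.
#' @param anammox_y_n Optional anammox nitrite-yield override (e.g. the
#'   trait-table value 0.0133, or a larger value for the
#'   superior-nitrite-competitor scenario).
#' @param anammox_k_no2 Optional anammox-specific nitrite half-saturation
#'   (uM), overriding the shared value (affinity-based competitive
#'   advantage).
#' @return An object of class `nf_community`: list of
#'   [functional_type()] objects plus shared metadata.
#' @examples
#' comm <- community()
#' trait_table(comm)
#' @export
community <- function(y_base = 0.25, d = 0.1, kinetics = NULL,
                      om_formula = marine_om_formula(), anammox_y_n = NULL,
                      anammox_k_no2 = NULL) {
  kin <- kinetics %||% default_kinetics(d)
  budgets <- metabolic_budgets(y_base, om_formula, include_anammox = TRUE,
                               anammox_y_n = anammox_y_n)
  types <- purrr::map(seq_len(nrow(budgets)), function(i) {
    functional_type(budgets[i, ], kin, d)
  })
  names(types) <- budgets$metabolism
  if (!is.null(anammox_k_no2)) {
    stopifnot(anammox_k_no2 > 0)
    types$anammox$kinetics$k[["no2"]] <- anammox_k_no2
  }
  structure(list(
    types = types,
    budgets = budgets,
    kinetics = kin,
    d = d,
    y_base = y_base,
    om_formula = as_elemental_formula(om_formula)
  ), class = "nf_community")
}

#' @export
print.nf_community <- function(x, ...) {
  cat("<nf_community> ", length(x$types), " functional types (",
      paste(names(x$types), collapse = ", "), ")\n",
      "  y_base = ", x$y_base, ", d = ", x$d, " d^-1, v_max = ",
      signif(x$kinetics$v_max, 5), " d^-1\n", sep = "")
  invisible(x)
}

#' Restrict a community to a subset of functional types
#'
#' Useful for single-population runs with closed-form steady states.
#'
#' @param comm An [community()].
#' @param labels Type labels to keep.
#' @return An `nf_community` containing only the requested types.
#' @export
community_subset <- function(comm, labels) {
  stopifnot(all(labels %in% names(comm$types)))
  comm$types <- comm$types[labels]
  comm$budgets <- comm$budgets[comm$budgets$metabolism %in% labels, ]
  comm
}

#' Trait table of a community
#'
#' One row per functional type and required resource, with the yield, shared
#' kinetics, subsistence concentration, and (for heterotrophs) the
#' consumption vector.
#'
#' @param comm An [community()] object.
#' @return A tibble with columns `metabolism`, `resource`, `y`, `v_max`, `k`,
#'   `rstar`, `cv` (step consumption vector; `NA` for anammox), `cv_full`
#'   (full-pathway value for `denit1`, otherwise `NA`).
#' @export
trait_table <- function(comm) {
  purrr::map_dfr(comm$types, function(ft) {
    rs <- subsistence_concentration(ft)
    cv <- if (is.na(ft$budget$y_om)) NA_real_ else consumption_vector(ft)
    cvf <- if (ft$label == "denit1") {
      consumption_vector(ft, "full", comm$om_formula)
    } else NA_real_
    tibble::tibble(
      metabolism = ft$label,
      resource = ft$required,
      y = unname(ft$yields),
      v_max = ft$kinetics$v_max,
      k = unname(ft$kinetics$k),
      rstar = unname(rs),
      cv = cv,
      cv_full = cvf
    )
  })
}

#' @rdname trait_table
#' @param x An `nf_community`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.nf_community <- function(x, ...) trait_table(x)
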