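#' Named model scenarios
#'
#' Resolves a scenario specification to a fully parameterized community and
#' chemostat configuration template. Available scenarios:
#' * `"default"`: four types; anammox yields from the measured budget
#'   (nitrite yield 1/80.7), so anammox is the weakest nitrite competitor.
#' * `"anammox-superior"`: anammox granted a nitrite subsistence
#'   concentration just below the nitrite ammonifier's
#'   (`NO2*_anammox = anammox_advantage * NO2*_DNRA`), implemented either by
#'   raising its nitrite yield (`mechanism = "yield"`, the default) or by
#'   lowering its nitrite half-saturation constant
#'   (`mechanism = "affinity"`); all other traits unchanged. Note that while
#'   the three-type steady state exists in a narrow supply-ratio window
#'   under this scenario (see [three_type_window()]), it is dynamically
#'   unstable: the system is bistable between denitrification+anammox and
#'   DNRA+anammox states, with a sharp transition in supply-ratio space.
#' * `"anammox-table1"`: as default but with the trait-table anammox nitrite
#'   yield (0.0133) instead of the budget value.
#'
#' @param name Scenario name.
#' @param y_base Baseline carbon-use efficiency in \[0.2, 0.3\].
#' @param d Dilution rate (per day).
#' @param anammox_advantage For `"anammox-superior"`: ratio of the anammox
#'   nitrite R* to the nitrite ammonifier's (must be < 1; default 0.9).
#' @param mechanism For `"anammox-superior"`: how the advantage is realized,
#'   `"yield"` or `"affinity"`.
#' @param nh4_supply_ratio Ammonium-to-nitrite supply ratio; `NULL` uses the
#'   budget-derived default of [nh4_supply_ratio()].
#' @param ... Further arguments stored in the configuration template and
#'   passed to [chemostat_config()] by [run_scenario_point()].
#' @return A list of class `nf_scenario`: `name`, `community`,
#'   `config_args` (supply-independent configuration arguments), and the
#'   resolved parameter set.
#' @examples
#' sc <- scenario("default")
#' trait_table(sc$community)
#' @export
scenario <- function(name = c("default", "anammox-superior", "anammox-table1"),
                     y_base = 0.25, d = 0.1, anammox_advantage = 0.9,
                     mechanism = c("yield", "affinity"),
                     nh4_supply_ratio = NULL, ...) {
  name <- match.arg(name)
  mechanism <- match.arg(mechanism)
  anammox_y_n <- NULL
  anammox_k_no2 <- NULL
  if (name == "anammox-table1") anammox_y_n <- 0.0133
  if (name == "anammox-superior") {
    if (!is.numeric(anammox_advantage) || anammox_advantage <= 0 ||
        anammox_advantage >= 1) {
      stop("anammox_advantage must lie in (0, 1)", call. = FALSE)
    }
    base <- community(y_base = y_base, d = d)
    rstar_target <- anammox_advantage *
      subsistence_concentration(base$types$dnra, "no2")
    v <- base$kinetics$v_max
    if (mechanism == "yield") {
      k_no2 <- base$kinetics$k[["no2"]]
      # invert R* = K d/(y v - d) for the yield achieving the target R*
      anammox_y_n <- unname((d + k_no2 * d / rstar_target) / v)
    } else {
      y_n <- base$types$anammox$yields[["no2"]]
      anammox_k_no2 <- unname(rstar_target * (y_n * v - d) / d)
    }
  }
  comm <- community(y_base = y_base, d = d, anammox_y_n = anammox_y_n,
                    anammox_k_no2 = anammox_k_no2)
  r <- nh4_supply_ratio %||% nitrofate::nh4_supply_ratio(y_base)
  structure(list(
    name = name,
    community = comm,
    config_args = c(list(d = d, nh4_supply_ratio = r), list(...)),
    parameters = list(y_base = y_base, d = d, anammox_y_n = anammox_y_n,
                      anammox_k_no2 = anammox_k_no2,
                      mechanism = if (name == "anammox-superior") mechanism
                        else NA_character_,
                      anammox_advantage =
                        if (name == "anammox-superior") anammox_advantage
                        else NA_real_,
                      nh4_supply_ratio = r)
  ), class = "nf_scenario")
}

#' @export
print.nf_scenario <- function(x, ...) {
  cat("<nf_scenario> '", x$name, "'\n  y_base = ", x$parameters$y_base,
      ", d = ", x$parameters$d, " d^-1, NH4+ supply ratio = ",
      signif(x$parameters$nh4_supply_ratio, 5), "\n", sep = "")
  invisible(x)
}

#' Run one supply point of a scenario
#'
#' @param sc An [scenario()].
#' @param om_in,no2_in Supply concentrations (uM N).
#' @param ... Overrides passed to [chemostat_config()].
#' @return An [steady_state()] record.
#' @export
run_scenario_point <- function(sc, om_in, no2_in, ...) {
  args <- utils::modifyList(sc$config_args,
                            c(list(om_in = om_in, no2_in = no2_in), list(...)))
  steady_state(sc$community, config = do.call(chemostat_config, args))
}

#' Serialize / restore a scenario specification
#'
#' Scenario specifications round-trip through a structured text (YAML) file,
#' so that any run can be reproduced from its configuration alone.
#'
#' @param sc An [scenario()].
#' @param path File path.
#' @return `write_scenario_config` invisibly returns `path`;
#'   `read_scenario_config` returns the restored [scenario()].
#' @export
write_scenario_config <- function(sc, path) {
  spec <- list(
    name = sc$name,
    y_base = sc$parameters$y_base,
    d = sc$parameters$d,
    nh4_supply_ratio = sc$parameters$nh4_supply_ratio,
    anammox_advantage = sc$parameters$anammox_advantage,
    mechanism = sc$parameters$mechanism
  )
  yaml::write_yaml(spec, path, precision = 15)
  invisible(path)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  spec <- yaml::read_yaml(path)
  adv <- spec$anammox_advantage
  if (is.null(adv) || is.na(adv)) adv <- 0.9
  mech <- spec$mechanism
  if (is.null(mech) || is.na(mech)) mech <- "yield"
  scenario(name = spec$name, y_base = spec$y_base, d = spec$d,
           anammox_advantage = adv, mechanism = mech,
           nh4_supply_ratio = spec$nh4_supply_ratio)
}

#' Run manifest
#'
#' A structured record of the resolved parameters, tolerances, package
#' version and convergence summaries of a set of runs — sufficient to
#' re-execute them bit-identically (the model is deterministic; randomized
#' inocula carry their seed).
#'
#' @param sc The [scenario()] that was run.
#' @param results A sweep/transect tibble.
#' @param seed Optional seed used for randomized inocula.
#' @param wall_time Optional elapsed seconds.
#' @return A list of class `nf_manifest`; write with [yaml::write_yaml()].
#' @export
run_manifest <- function(sc, results, seed = NULL, wall_time = NULL) {
  structure(list(
    package = "nitrofate",
    version = as.character(utils::packageVersion("nitrofate")),
    scenario = sc$parameters,
    scenario_name = sc$name,
    seed = seed,
    n_runs = nrow(results),
    n_converged = sum(results$converged),
    max_residual = max(results$residual_norm),
    wall_time_s = wall_time,
    units = "concentrations uM N (DIC uM C); rates per day"
  ), class = "nf_manifest")
}

#' Small scenario bundles for testing
#'
#' Pre-packaged configurations with oracle expectations attached: at the
#' `"unit"` level, single-population chemostats whose steady state has a
#' closed form (limiting resource drawn down to R*, biomass = yield times
#' the supply surplus); at the `"integration"` level, a small supply sweep
#' and transect with regime labels expected from consumption-vector
#' geometry.
#'
#' @param level `"unit"` or `"integration"`.
#' @return A list of fixtures; each has `description`, the inputs, and an
#'   `expected` list.
#' @export
fixture_bundle <- function(level = c("unit", "integration")) {
  level <- match.arg(level)
  comm <- community()
  if (level == "unit") {
    dnra <- comm$types$dnra
    om_star <- subsistence_concentration(dnra, "om")
    no2_star <- subsistence_concentration(dnra, "no2")
    list(
      `dnra-solo-om-limited` = list(
        description = "single nitrite ammonifier, OM limiting",
        types = "dnra", om_in = 2, no2_in = 100,
        expected = list(
          om = unname(om_star),
          biomass = unname(dnra$yields[["om"]] * (2 - om_star))
        )
      ),
      `dnra-solo-no2-limited` = list(
        description = "single nitrite ammonifier, NO2- limiting",
        types = "dnra", om_in = 40, no2_in = 4,
        expected = list(
          no2 = unname(no2_star),
          biomass = unname(dnra$yields[["no2"]] * (4 - no2_star))
        )
      ),
      `washout` = list(
        description = "no electron donor: everything washes out",
        types = nf_types(), om_in = 0, no2_in = 25,
        expected = list(biomass = 0, no2 = 25)
      )
    )
  } else {
    cv_den <- pathway_cv(comm)
    cv_dnra <- consumption_vector(comm$types$dnra)
    rho <- c(0.4, 0.8, 1.4, 2.2) * cv_den
    rho <- c(rho, 1.05 * cv_dnra, 1.4 * cv_dnra)
    list(
      `transect-9pt` = list(
        description = "9-point transect spanning the three regimes",
        no2_in = 25,
        om_in = 25 * sort(c(rho, (cv_den + cv_dnra) / 2, 0.6 * cv_den,
                            1.6 * cv_den)),
        expected = list(
          regimes = c("denit", "coexist", "dnra"),
          boundary_rho = c(cv_den, cv_dnra)
        )
      ),
      `sweep-5x5` = list(
        description = "5x5 supply sweep straddling both CV boundaries",
        om_in = seq(0.8, 6.4, length.out = 5),
        no2_in = seq(8, 28, length.out = 5),
        expected = list(boundary_rho = c(cv_den, cv_dnra))
      )
    )
  }
}
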