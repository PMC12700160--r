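#' Default ammonium supply ratio
#'
#' Nitrite entering the chemostat represents the product of implied upstream
#' nitrate reduction (NO3- to NO2-, 2 electrons per N) by heterotrophs. The
#' ammonium released by that implied step is co-supplied in proportion:
#' `NH4_in = r * NO2_in`, with `r` the ammonium-to-nitrite ratio of the
#' generated NO3- to NO2- budget at the denitrifier synthesis fraction.
#'
#' @param y_base Baseline carbon-use efficiency (sets the denitrifier
#'   synthesis fraction).
#' @param om_formula Organic-matter composition.
#' @return The ratio `r` (mol NH4+ per mol NO2- supplied).
#' @export
nh4_supply_ratio <- function(y_base = 0.25, om_formula = marine_om_formula()) {
  fs <- fs_at_baseline(y_base)[["denit"]]
  b <- heterotroph_budget("NO3->NO2", fs, om_formula)
  r <- b$nh4 / b$no2  # NH4+ released per NO2- produced
  if (r < 0) stop("derived ammonium supply ratio is negative", call. = FALSE)
  unname(r)
}

#' Chemostat configuration
#'
#' Collects supply concentrations, dilution rate, initial conditions and
#' integration controls for a virtual chemostat run. All nitrogen pools and
#' biomasses are in uM N; organic matter is tracked in uM N of OM (1 N per
#' mol OM for the default composition); DIC in uM C; time in days.
#'
#' @param om_in,no2_in Inflow concentrations (uM N).
#' @param nh4_in Inflow ammonium (uM N). If `NULL`, computed as
#'   `nh4_supply_ratio * no2_in`.
#' @param nh4_supply_ratio Ratio used when `nh4_in` is `NULL`; `NULL` means
#'   the budget-derived default of [nh4_supply_ratio()].
#' @param d Dilution rate (per day).
#' @param dic_in Inflow DIC (uM C); a large background so DIC never limits.
#' @param inoculum Initial biomass of each seeded type (uM N); scalar or
#'   named vector.
#' @param t_max Maximum integration horizon (days).
#' @param tol_ss Steady-state tolerance: maximum relative time-derivative.
#' @param extinction_threshold Biomass (uM N) below which a declining type is
#'   clamped to zero (competitive exclusion is asymptotic in ODEs; a
#'   threshold realizes it in finite time).
#' @return A list of class `nf_config`.
#' @export
chemostat_config <- function(om_in, no2_in, nh4_in = NULL,
                             nh4_supply_ratio = NULL, d = 0.1,
                             dic_in = 2000, inoculum = 1e-3,
                             t_max = 50000, tol_ss = 1e-8,
                             extinction_threshold = 1e-10) {
  stopifnot(d > 0, om_in >= 0, no2_in >= 0, dic_in >= 0, t_max > 0)
  if (is.null(nh4_in)) {
    r <- nh4_supply_ratio %||% nitrofate::nh4_supply_ratio()
    if (r < 0) stop("nh4_supply_ratio must be non-negative", call. = FALSE)
    nh4_in <- r * no2_in
  }
  structure(list(
    om_in = om_in, no2_in = no2_in, nh4_in = nh4_in, d = d, dic_in = dic_in,
    inoculum = inoculum, t_max = t_max, tol_ss = tol_ss,
    extinction_threshold = extinction_threshold
  ), class = "nf_config")
}

# Internal: assemble the community into flat matrices for fast derivatives.
community_matrices <- function(comm) {
  pools <- nf_pools()
  n_t <- length(comm$types)
  M <- matrix(0, n_t, length(pools), dimnames = list(names(comm$types), pools))
  for (i in seq_len(n_t)) {
    M[i, ] <- unlist(comm$types[[i]]$budget[pools])
  }
  req <- purrr::map(comm$types, "required")
  yv <- purrr::map(comm$types, function(ft) ft$yields * ft$kinetics$v_max)
  kk <- purrr::map(comm$types, function(ft) ft$kinetics$k)
  list(M = M, req = req, yv = yv, kk = kk, pools = pools,
       labels = names(comm$types))
}

# Internal: growth rates of all types given pool concentrations (named).
community_mu <- function(mats, conc) {
  vapply(seq_along(mats$req), function(i) {
    r <- pmax(conc[mats$req[[i]]], 0)
    min(mats$yv[[i]] * r / (r + mats$kk[[i]]))
  }, numeric(1))
}

#' Chemostat time derivatives
#'
#' The coupled balance equations: for each population
#' \eqn{dB_i/dt = (\mu_i - d) B_i} with \eqn{\mu_i} from [growth_rate()], and
#' for each dissolved pool \eqn{dR_j/dt = d (R_{in,j} - R_j) + \sum_i m_{ij}
#' \mu_i B_i}, where \eqn{m_{ij}} are the signed budget coefficients, so
#' uptake of every consumed resource is tied to growth through the budget.
#' Total nitrogen obeys \eqn{d(\Sigma N)/dt = d (N_{in} - \Sigma N)} exactly:
#' the biological terms cancel because every budget is N-balanced.
#'
#' @param state Named state vector: biomasses (type labels) then pools
#'   (`om`, `no2`, `nh4`, `n2o_n`, `n2_n`, `no3`, `dic`).
#' @param config An [chemostat_config()].
#' @param comm An [community()].
#' @return Named vector of time derivatives (uM N per day).
#' @export
chemostat_derivatives <- function(state, config, comm) {
  mats <- community_matrices(comm)
  d_state(state, config, mats)
}

d_state <- function(state, config, mats) {
  n_t <- length(mats$labels)
  B <- state[seq_len(n_t)]
  conc <- state[n_t + seq_along(mats$pools)]
  names(conc) <- mats$pools
  mu <- community_mu(mats, conc)
  synth <- mu * pmax(B, 0)
  inflow <- c(om = config$om_in, no2 = config$no2_in, nh4 = config$nh4_in,
              n2o_n = 0, n2_n = 0, no3 = 0, dic = config$dic_in)
  dpool <- config$d * (inflow - conc) + drop(crossprod(mats$M, synth))
  dB <- (mu - config$d) * B
  out <- c(dB, dpool)
  names(out) <- c(mats$labels, mats$pools)
  out
}

#' Integrate the chemostat to steady state
#'
#' Stiff-capable integration (`deSolve::lsoda`) in successive windows until
#' the maximum relative time derivative falls below `tol_ss`, or `t_max` is
#' reached (the record is then flagged non-converged). Populations declining
#' below the extinction threshold between windows are clamped to zero.
#'
#' @param comm An [community()].
#' @param config An [chemostat_config()]; alternatively pass `om_in` /
#'   `no2_in` / `...` directly and a config is built.
#' @param om_in,no2_in,... Convenience: forwarded to [chemostat_config()]
#'   when `config` is `NULL`.
#' @return An object of class `nf_steady_state`: list with `state` (named
#'   vector), `biomass`, `pools`, `mu`, `limiting` (per surviving type),
#'   `fluxes` (tibble of per-type synthesis and per-pool net biological
#'   fluxes), `converged`, `t_steady`, `residual_norm`, plus the `config` and
#'   community metadata.
#' @examples
#' \donttest{
#' comm <- community()
#' ss <- steady_state(comm, om_in = 2, no2_in = 25)
#' glance(ss)
#' }
#' @export
steady_state <- function(comm, config = NULL, om_in = NULL, no2_in = NULL,
                         ...) {
  if (is.null(config)) {
    config <- chemostat_config(om_in = om_in, no2_in = no2_in, ...)
  }
  mats <- community_matrices(comm)
  n_t <- length(mats$labels)
  inoc <- config$inoculum
  if (length(inoc) == 1L) inoc <- setNames(rep(inoc, n_t), mats$labels)
  x <- c(inoc[mats$labels],
         c(om = config$om_in, no2 = config$no2_in, nh4 = config$nh4_in,
           n2o_n = 0, n2_n = 0, no3 = 0, dic = config$dic_in))

  deriv_fun <- function(t, y, parms) {
    list(d_state(y, config, mats))
  }
  rel_norm <- function(y) {
    dy <- d_state(y, config, mats)
    max(abs(dy) / (abs(y) + 1e-6))
  }

  t_now <- 0
  converged <- FALSE
  windows <- c(250, 250, 500, 1000, 2000, 4000)
  repeat {
    len <- if (length(windows)) windows[1] else 8000
    windows <- windows[-1]
    len <- min(len, config$t_max - t_now)
    sol <- deSolve::lsoda(y = x, times = c(0, len), func = deriv_fun,
                          parms = NULL, rtol = 1e-8, atol = 1e-10,
                          maxsteps = 5e5)
    x_new <- sol[nrow(sol), -1]
    names(x_new) <- names(x)
    if (any(x_new < -1e-6)) {
      stop("integration produced negative state components beyond tolerance",
           call. = FALSE)
    }
    x_new[x_new < 0] <- 0
    # competitive exclusion: clamp vanishing populations
    b <- x_new[seq_len(n_t)]
    b[b < config$extinction_threshold] <- 0
    x_new[seq_len(n_t)] <- b
    x <- x_new
    t_now <- t_now + len
    if (rel_norm(x) < config$tol_ss) {
      converged <- TRUE
      break
    }
    if (t_now >= config$t_max) break
  }

  B <- x[seq_len(n_t)]
  conc <- x[n_t + seq_along(mats$pools)]
  names(conc) <- mats$pools
  mu <- setNames(community_mu(mats, conc), mats$labels)
  synth <- mu * B
  limiting <- purrr::imap_chr(comm$types, function(ft, lab) {
    if (B[[lab]] > 0) limiting_resource(ft, conc) else NA_character_
  })
  # per-type resource consumption and production fluxes, uM N per day
  flux <- tibble::tibble(
    metabolism = rep(mats$labels, each = length(mats$pools)),
    pool = rep(mats$pools, times = n_t),
    flux = as.vector(t(mats$M * synth))
  )
  structure(list(
    state = x, biomass = B, pools = conc, mu = mu, synthesis = synth,
    limiting = limiting, fluxes = flux,
    converged = converged, t_steady = t_now, residual_norm = rel_norm(x),
    config = config,
    community = list(labels = mats$labels, d = comm$d, y_base = comm$y_base)
  ), class = "nf_steady_state")
}

#' @export
print.nf_steady_state <- function(x, ...) {
  cat("<nf_steady_state> ",
      if (x$converged) "converged" else "NOT converged",
      " at t = ", x$t_steady, " d (residual ",
      format(x$residual_norm, digits = 3), ")\n", sep = "")
  cat("  biomass (uM N): ",
      paste(names(x$biomass), signif(x$biomass, 4), sep = "=", collapse = ", "),
      "\n  pools (uM): ",
      paste(names(x$pools), signif(x$pools, 4), sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @rdname steady_state
#' @param x An `nf_steady_state`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.nf_steady_state <- function(x, ...) {
  tibble::tibble(
    component = names(x$state),
    kind = rep(c("biomass", "pool"),
               c(length(x$biomass), length(x$pools))),
    value = unname(x$state)
  )
}

#' @rdname steady_state
#' @exportS3Method generics::glance
glance.nf_steady_state <- function(x, ...) {
  tibble::tibble(
    om_in = x$config$om_in, no2_in = x$config$no2_in,
    nh4_in = x$config$nh4_in, d = x$config$d,
    !!!setNames(as.list(x$biomass), paste0("b_", names(x$biomass))),
    !!!as.list(x$pools),
    converged = x$converged, t_steady = x$t_steady,
    residual_norm = x$residual_norm
  )
}

#' Steady-state mass-balance report
#'
#' At steady state the dilution outflow of total nitrogen (all dissolved N
#' pools, N2 included, plus biomass N) must equal the nitrogen supply, and
#' likewise for carbon (OM carbon, DIC, biomass carbon). Residuals are
#' relative to the supply flux.
#'
#' @param record An [steady_state()] result.
#' @param om_formula,biomass Compositions (for C bookkeeping).
#' @param tol Flag threshold on the relative residuals.
#' @return A tibble with `element`, `supply` (uM per day), `outflow`,
#'   `residual` (relative), `ok`.
#' @export
mass_balance <- function(record, om_formula = marine_om_formula(),
                         biomass = biomass_formula(), tol = 1e-6) {
  cfg <- record$config
  om <- as_elemental_formula(om_formula)
  bio <- as_elemental_formula(biomass)
  c_per_n_om <- om[["c"]] / om[["n"]]
  c_per_n_bio <- bio[["c"]] / bio[["n"]]
  p <- record$pools
  n_in <- cfg$d * (cfg$om_in + cfg$no2_in + cfg$nh4_in)
  n_out <- cfg$d * (sum(p[c("om", "no2", "nh4", "n2o_n", "n2_n", "no3")]) +
                      sum(record$biomass))
  c_in <- cfg$d * (cfg$om_in * c_per_n_om + cfg$dic_in)
  c_out <- cfg$d * (p[["om"]] * c_per_n_om + p[["dic"]] +
                      sum(record$biomass) * c_per_n_bio)
  res <- tibble::tibble(
    element = c("N", "C"),
    supply = c(n_in, c_in),
    outflow = c(n_out, c_out),
    residual = abs(c(n_in - n_out, c_in - c_out)) / c(n_in, c_in)
  )
  res$ok <- res$residual <= tol
  res
}
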