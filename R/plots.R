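#' Plot a transect
#'
#' Three stacked panels in the style of a supply-ratio transect figure:
#' functional-type biomasses, the percentage of nitrite reduced by each
#' pathway, and the ammonium-regeneration versus N2 production fluxes whose
#' crossing marks net zero nitrogen loss.
#'
#' @param object An `nf_transect` from [transect()].
#' @param ... Unused.
#' @return A [ggplot2::ggplot] object (facetted).
#' @exportS3Method ggplot2::autoplot
autoplot.nf_transect <- function(object, ...) {
  biom <- object |>
    dplyr::select(.data$rho, dplyr::starts_with("b_")) |>
    tidyr::pivot_longer(-"rho", names_to = "series", names_prefix = "b_",
                        values_to = "value") |>
    dplyr::mutate(panel = "biomass (uM N)")
  fate <- object |>
    dplyr::filter(.data$active) |>
    dplyr::select(.data$rho, .data$f_dnra, .data$f_denit, .data$f_anammox) |>
    tidyr::pivot_longer(-"rho", names_to = "series", names_prefix = "f_",
                        values_to = "value") |>
    dplyr::mutate(value = 100 * .data$value,
                  panel = "NO2- reduced (%)")
  prodn <- object |>
    dplyr::select(.data$rho, `NH4+` = .data$nh4_production,
                  N2 = .data$n2_production) |>
    tidyr::pivot_longer(-"rho", names_to = "series", values_to = "value") |>
    dplyr::mutate(panel = "production (uM N / d)")
  dat <- dplyr::bind_rows(biom, fate, prodn)
  cv <- attr(object, "cv_lines")
  p <- ggplot2::ggplot(dat, ggplot2::aes(.data$rho, .data$value,
                                         colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "OM : NO2- supply ratio (mol N / mol N)", y = NULL,
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(cv)) {
    p <- p + ggplot2::geom_vline(xintercept = unname(cv), linetype = "dashed",
                                 colour = "grey50")
  }
  p
}

#' Plot a supply-sweep regime map
#'
#' Tiles of the simulated regime across the OM and NO2- supply grid, with
#' the heterotroph consumption vectors overlaid as lines through the origin.
#'
#' @param object An `nf_sweep` from [supply_sweep()].
#' @param ... Unused.
#' @return A [ggplot2::ggplot] object.
#' @exportS3Method ggplot2::autoplot
autoplot.nf_sweep <- function(object, ...) {
  cv <- attr(object, "cv_lines")
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$no2_in, .data$om_in,
                                            fill = .data$regime)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "NO2- supply (uM N)", y = "OM supply (uM N)",
                  fill = "regime") +
    ggplot2::theme_minimal()
  if (!is.null(cv)) {
    p <- p +
      ggplot2::geom_abline(slope = unname(cv), intercept = 0,
                           linetype = c("dashed", "dotdash"),
                           colour = "white")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
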