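#' Plot a labelling screen
#'
#' Volcano-style view of a screening result: odds-ratio contrast between the
#' 13C and 12C strata against the Breslow-Day evidence, coloured by the
#' directional call.
#'
#' @param object A [run_labelling_screen()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sip_screen <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(
    df,
    ggplot2::aes(
      x = log2(.data$or_c13 / .data$or_c12),
      y = -log10(pmax(.data$p_value, 1e-300)),
      colour = .data$direction
    )
  ) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(
      values = c(labelled = "#c0392b", unlabelled = "#2980b9", none = "grey60")
    ) +
    ggplot2::labs(
      x = expression(log[2] * " OR ratio (" ^ 13 * "C / " ^ 12 * "C)"),
      y = expression(-log[10] ~ italic(p)),
      colour = "call",
      title = "Heavy-fraction enrichment screen"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the composition of the labelled community
#'
#' @param object An [aggregate_labelled_taxa()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sip_composition <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(
    df,
    ggplot2::aes(
      x = stats::reorder(.data$group, .data$rel_abundance),
      y = .data$rel_abundance
    )
  ) +
    ggplot2::geom_col(fill = "#c0392b") +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = attr(object, "rank") %||% "group",
      y = "relative abundance among labelled taxa",
      title = "Composition of the labelled community (13C heavy fraction)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a fluorescence standard curve
#'
#' @param object A [fit_standard_curve()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.standard_curve <- function(object, ...) {
  ggplot2::ggplot(
    object$data,
    ggplot2::aes(x = .data$concentration, y = .data$fluorescence)
  ) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(
      slope = object$slope, intercept = object$intercept, colour = "#2980b9"
    ) +
    ggplot2::labs(
      x = "MUF concentration (uM)", y = "fluorescence (AU)",
      title = sprintf("Standard curve (r^2 = %.4f)", object$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' Plot simulated gradient profiles
#'
#' Expected per-fraction DNA mass of labelled and unlabelled taxa in the 12C
#' and 13C incubations of a simulated experiment, showing the upward
#' buoyant-density shift of labelled DNA.
#'
#' @param x A [simulate_sip_experiment()] result.
#' @return A ggplot object.
#' @export
plot_gradient <- function(x) {
  stopifnot(inherits(x, "sip_experiment"))
  cfg <- x$config
  mids <- (cfg$breaks[-1] + cfg$breaks[-length(cfg$breaks)]) / 2
  per_group <- function(comp, isotope) {
    purrr::map(c(FALSE, TRUE), function(lab) {
      w <- x$truth$abundance * (x$truth$labelled == lab)
      # expected mass (not renormalised composition) per fraction
      rho <- buoyant_density(
        x$truth$gc,
        if (isotope == "C13") x$truth$atom_excess else 0
      )
      mass <- fractionate_taxon(rho, cfg$sigma_rho, cfg)
      mass <- matrix(mass, nrow = nrow(x$truth))
      tibble::tibble(
        isotope = isotope,
        labelled = lab,
        density = mids,
        mass = colSums(mass * w)
      )
    }) |> purrr::list_rbind()
  }
  df <- dplyr::bind_rows(per_group(NULL, "C12"), per_group(NULL, "C13"))
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$density, y = .data$mass, colour = .data$labelled)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(
      xintercept = c(cfg$light_density, cfg$heavy_density), linetype = 3
    ) +
    ggplot2::facet_wrap(~isotope) +
    ggplot2::labs(
      x = "buoyant density (g/mL)", y = "expected DNA mass",
      colour = "truth: labelled",
      title = "Simulated gradient profiles (dotted: sequenced fractions)"
    ) +
    ggplot2::theme_minimal()
}
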