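#' Plot a stability surface from a phase-space scan
#'
#' Tile map of E_b over (ditopic angle, polytopic angle) for one topology
#' and torsion state, mirroring an angle-energy stability surface. Points
#' above `cap` are shown in the cap colour (high-energy region).
#'
#' @param results a `cage_scan` tibble.
#' @param topology topology name to plot.
#' @param torsion torsion state to plot.
#' @param cap colour-scale cap on E_b (kJ/mol).
#' @return a ggplot object.
#' @export
plot_stability_surface <- function(results, topology,
                                   torsion = "on", cap = 1) {
  sub <- filter(results, .data$topology == !!topology,
                .data$torsion_state == !!torsion)
  if (nrow(sub) == 0) abort(paste0("no results for ", topology))
  poly_col <- if (all(is.na(sub$tritopic_angle))) "tetratopic_angle" else "tritopic_angle"
  sub$polytopic_angle <- sub[[poly_col]]
  x_lab <- if (all(is.na(sub$polytopic_angle))) NULL else poly_col
  ggplot2::ggplot(sub, ggplot2::aes(
    x = .data$ditopic_angle, y = .data$polytopic_angle,
    fill = pmin(.data$E_b, cap))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "E_b (kJ/mol)") +
    ggplot2::labs(x = "ditopic angle (deg)",
                  y = paste(sub("_angle", "", poly_col), "angle (deg)"),
                  title = paste0(topology, ", torsion ", torsion)) +
    ggplot2::theme_minimal()
}

#' Plot an accessible topology map
#'
#' Tile map of the smallest stable topology (or outcome) at each grid
#' point, the discrete accessible-topology view of a classified scan.
#'
#' @param map_tbl output of [accessible_map()].
#' @param fill `"smallest_stable"` or `"outcome"`.
#' @return a ggplot object.
#' @export
plot_accessible_map <- function(map_tbl, fill = c("smallest_stable", "outcome")) {
  fill <- match.arg(fill)
  ggplot2::ggplot(map_tbl, ggplot2::aes(
    x = .data$ditopic_angle, y = .data$polytopic_angle,
    fill = .data[[fill]])) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::labs(x = "ditopic angle (deg)", y = "polytopic angle (deg)",
                  fill = fill) +
    ggplot2::theme_minimal()
}

#' Plot the percent-selected curve
#'
#' Percentage of building-block combinations with exactly one stable
#' topology as a function of the accessibility threshold.
#'
#' @param curve output of [percent_selected()] (optionally row-bound over
#'   families/torsion states with extra grouping columns).
#' @param colour optional column name to colour by.
#' @return a ggplot object.
#' @export
plot_percent_selected <- function(curve, colour = NULL) {
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$threshold,
                                           y = .data$percent_selected))
  if (!is.null(colour)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(colour = .data[[colour]]))
  } else {
    p <- p + ggplot2::geom_line()
  }
  p + ggplot2::labs(x = "E_b threshold (kJ/mol)", y = "% selected") +
    ggplot2::theme_minimal()
}

#' @rdname plot_stability_surface
#' @param object a `cage_scan`.
#' @param ... passed to [plot_stability_surface()].
#' @export
autoplot.cage_scan <- function(object, ...) {
  args <- list(...)
  if (is.null(args$topology)) {
    args$topology <- object$topology[1]
  }
  do.call(plot_stability_surface, c(list(results = object), args))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
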