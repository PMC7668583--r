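#' @importFrom ggplot2 ggplot aes geom_tile geom_line geom_col geom_point
#'   scale_fill_gradient2 scale_fill_manual labs theme_minimal
NULL

#' Plot a tabulated sigmoid potential
#'
#' Energy (red) and force magnitude (green) against distance, the
#' standard way the restraint potential is presented.
#'
#' @param object A `tabulated_potential`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tabulated_potential <- function(object, ...) {
  df <- tidyr::pivot_longer(
    dplyr::mutate(as_tibble(object), force = -.data$neg_deriv),
    c("energy", "force"), names_to = "curve")
  ggplot(df, aes(x = .data$r, y = .data$value, colour = .data$curve)) +
    geom_line() +
    ggplot2::scale_colour_manual(values = c(energy = "#c0392b",
                                            force = "#27ae60")) +
    labs(x = "distance r (nm)", y = "kJ/mol | kJ/mol/nm",
         colour = NULL, title = "Sigmoid restraint potential") +
    theme_minimal()
}

#' Plot an RMSD heatmap across replicas and time
#'
#' Time on x, replica index on y; RMSDs below 4 Angstrom render blue
#' (native-like), above toward red.
#'
#' @param object An `rmsd_heatmap` tibble.
#' @param midpoint Colour midpoint in Angstrom (default 4).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rmsd_heatmap <- function(object, midpoint = 4, ...) {
  ggplot(object, aes(x = .data$time_ns, y = .data$replica,
                     fill = .data$rmsd)) +
    geom_tile() +
    scale_fill_gradient2(low = "#2166ac", mid = "#f7f7f7", high = "#b2182b",
                         midpoint = midpoint, name = "RMSD (Å)") +
    labs(x = "time (ns)", y = "replica (by temperature)") +
    theme_minimal()
}

#' Plot an enrichment/depletion histogram
#'
#' Positive Delta N bins (enrichment) in green, negative (depletion) in
#' red.
#'
#' @param object A `delta_histogram`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.delta_histogram <- function(object, ...) {
  df <- dplyr::mutate(as_tibble(object),
                      sign = ifelse(.data$delta_n >= 0, "enriched",
                                    "depleted"))
  ggplot(df, aes(x = .data$mid, y = .data$delta_n, fill = .data$sign)) +
    geom_col(width = (df$bin_hi - df$bin_lo)[1]) +
    scale_fill_manual(values = c(enriched = "#27ae60",
                                 depleted = "#c0392b"), guide = "none") +
    labs(x = "RMSD (Å)", y = expression(Delta * N)) +
    theme_minimal()
}

#' Plot a local-accuracy map
#'
#' Top frames (rows, ranked by GDT_HA) against residues (columns), tiles
#' coloured by displacement class.
#'
#' @param object A `local_accuracy` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.local_accuracy <- function(object, ...) {
  edges <- attr(object, "class_edges") %||% c(1, 2, 4, 8)
  lab <- c(sprintf("< %g Å", edges[1]),
           sprintf("%g - %g Å", utils::head(edges, -1), edges[-1]),
           sprintf("> %g Å", edges[length(edges)]))
  df <- dplyr::mutate(as_tibble(object),
                      class_f = factor(lab[.data$class + 1], levels = lab))
  pal <- grDevices::colorRampPalette(c("#2166ac", "#f7f7f7", "#b2182b"))
  ggplot(df, aes(x = .data$res_id, y = .data$rank, fill = .data$class_f)) +
    geom_tile(colour = "grey80") +
    scale_fill_manual(values = stats::setNames(pal(length(lab)), lab),
                      name = "Cα displacement", drop = FALSE) +
    ggplot2::scale_y_reverse() +
    labs(x = "residue", y = "frame rank (by GDT_HA)") +
    theme_minimal()
}

#' Plot a temperature ladder
#'
#' @param object A `temperature_ladder`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.temperature_ladder <- function(object, ...) {
  ggplot(object, aes(x = .data$replica, y = .data$temperature)) +
    geom_point() + geom_line(alpha = 0.4) +
    labs(x = "replica index", y = "temperature (K)") +
    theme_minimal()
}
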