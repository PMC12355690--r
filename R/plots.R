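#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a synthon ranking as an energy bar chart
#'
#' @param object a `cocryst_synthons` tibble from [rank_synthons()].
#' @param ... ignored.
#' @return a ggplot: one bar per synthon, coloured by interaction type.
#' @method autoplot cocryst_synthons
#' @export
autoplot.cocryst_synthons <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$rank_f <- factor(df$rank)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank_f, y = .data$e_total,
                                   fill = .data$type_label)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "synthon rank", y = "interaction energy (kcal/mol)",
                  fill = "type") +
    ggplot2::theme_minimal()
}

#' Plot a Wulff habit's facet area distribution
#'
#' @param object a `cocryst_habit` from [wulff_habit()].
#' @param ... ignored.
#' @return a ggplot bar chart of relative facet areas.
#' @method autoplot cocryst_habit
#' @export
autoplot.cocryst_habit <- function(object, ...) {
  df <- object$facets
  df$label <- sprintf("(%d %d %d)", df$h, df$k, df$l)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$label,
                                                      -.data$relative_area),
                                   y = .data$relative_area)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "facet family", y = "relative habit area") +
    ggplot2::theme_minimal()
}

#' Plot a surface height map
#'
#' Raster of the van der Waals height field relative to the average plane,
#' diverging palette centred on zero (regions above the average plane warm,
#' below cool).
#'
#' @param object a `cocryst_topology` from [topology_map()].
#' @param ... ignored.
#' @return a ggplot raster.
#' @method autoplot cocryst_topology
#' @export
autoplot.cocryst_topology <- function(object, ...) {
  ggplot2::ggplot(object$grid, ggplot2::aes(x = .data$s1, y = .data$s2,
                                            fill = .data$height)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "green", high = "red",
                                  midpoint = 0) +
    ggplot2::labs(x = "patch u", y = "patch v",
                  fill = "height (Å)",
                  title = sprintf("rugosity %.2f Å", object$rugosity)) +
    ggplot2::theme_minimal()
}

#' Plot complementarity screen outcomes per descriptor
#'
#' @param screen result tibble of [mc_screen()].
#' @return a ggplot tile map of PASS/FAIL per coformer and descriptor.
#' @export
plot_mc_screen <- function(screen) {
  desc <- c("s_axis", "s_over_l", "m_over_l", "no_fraction", "dipole")
  long <- tidyr::pivot_longer(
    screen[, c("coformer", paste0("pass_", desc))],
    cols = -"coformer", names_to = "descriptor", values_to = "pass"
  )
  long$descriptor <- sub("^pass_", "", long$descriptor)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$descriptor, y = .data$coformer,
                                     fill = .data$pass)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "seagreen",
                                          `FALSE` = "firebrick")) +
    ggplot2::labs(x = NULL, y = NULL, fill = "PASS") +
    ggplot2::theme_minimal()
}
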