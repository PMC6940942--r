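# ggplot2 views of the pipeline's result tables.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot a phospho-stoichiometry distribution
#'
#' @param object A `stoich_distribution` (from [stoichiometry_at_charge()] or
#'   [stoichiometry_from_occupancies()]); several time points may be row-bound.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.stoich_distribution <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$n_phospho,
                                            y = .data$fraction)) +
    ggplot2::geom_col(fill = "grey25") +
    ggplot2::labs(x = "phosphates per molecule", y = "fraction of molecules") +
    ggplot2::theme_minimal()
  if (!all(is.na(object$time_point)) &&
      dplyr::n_distinct(object$time_point) > 1) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$time_point))
  }
  p
}

#' Plot percent-of-maximum site kinetics
#'
#' @param object A `site_profiles` table from [percent_of_max()].
#' @param ... Unused.
#' @return A ggplot (one panel per residue, bars by time point with replicate
#'   SD whiskers).
#' @export
autoplot.site_profiles <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$time_point),
                                       y = .data$percent)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = pmax(.data$percent - .data$sd_percent, 0),
                                        ymax = .data$percent + .data$sd_percent),
                           width = 0.25) +
    ggplot2::facet_wrap(ggplot2::vars(.data$residue)) +
    ggplot2::labs(x = "time (h)", y = "percent of maximum") +
    ggplot2::theme_minimal()
}

#' Plot a simulated time course
#'
#' @param object A `phospho_timecourse` from [simulate_timecourse()].
#' @param ... Unused.
#' @return A ggplot of per-site occupancy trajectories.
#' @export
autoplot.phospho_timecourse <- function(object, ...) {
  ggplot2::ggplot(object$trajectories,
                  ggplot2::aes(x = .data$t, y = .data$p,
                               colour = .data$residue)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "time (h)", y = "site occupancy") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot a conservation profile
#'
#' @param object A `conservation_profile` from [conservation_table()].
#' @param ... Unused.
#' @return A ggplot of per-position information content with highlighted
#'   positions marked.
#' @export
autoplot.conservation_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position, y = .data$R_bits)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$highlighted), width = 1) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "goldenrod"),
                               guide = "none") +
    ggplot2::labs(x = "reference position", y = "information (bits)") +
    ggplot2::theme_minimal()
}

#' Stacked-letter logo plot
#'
#' Renders a [logo_table()] as stacked letters, tallest on top, heights in
#' bits.
#'
#' @param logo A [logo_table()] result.
#' @param positions Optional subset of reference positions to draw.
#' @return A ggplot.
#' @export
plot_logo <- function(logo, positions = NULL) {
  if (!is.null(positions)) {
    logo <- dplyr::filter(logo, .data$position %in% positions)
  }
  stacked <- logo |>
    dplyr::filter(.data$height > 0) |>
    dplyr::group_by(.data$position) |>
    dplyr::arrange(.data$height, .by_group = TRUE) |>
    dplyr::mutate(ymax = cumsum(.data$height),
                  ymid = .data$ymax - .data$height / 2) |>
    dplyr::ungroup()
  ggplot2::ggplot(stacked) +
    ggplot2::geom_text(ggplot2::aes(x = .data$position, y = .data$ymid,
                                    label = .data$letter,
                                    size = .data$height),
                       show.legend = FALSE) +
    ggplot2::scale_size_continuous(range = c(1, 6)) +
    ggplot2::labs(x = "reference position", y = "bits") +
    ggplot2::theme_minimal()
}
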