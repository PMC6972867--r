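# ggplot2 views of the main result types.

#' Plot a GA profiling matrix
#'
#' Site-by-amino-acid tile plot of grafted homo-hexapeptide mean RMSF, with
#' failing cells (at or above the constraint threshold) outlined.
#'
#' @param ga A `flap_ga_report`.
#' @return A ggplot object.
#' @export
plot_ga_matrix <- function(ga) {
  stopifnot(inherits(ga, "flap_ga_report"))
  df <- tidy(ga)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$name, y = .data$site_name,
                                   fill = .data$mean_rmsf)) +
    ggplot2::geom_tile(ggplot2::aes(colour = !.data$pass), linewidth = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = NA, `TRUE` = "red"),
                                 guide = "none") +
    ggplot2::scale_fill_viridis_c(name = "mean RMSF (Å)") +
    ggplot2::labs(x = "grafted homo-hexapeptide", y = "site") +
    ggplot2::theme_minimal()
}

#' Plot the site-selection funnel
#'
#' @param scan A `flap_scan_result`.
#' @return A ggplot object.
#' @export
plot_funnel <- function(scan) {
  stopifnot(inherits(scan, "flap_scan_result"))
  tot <- glance(scan)
  df <- tidyr::pivot_longer(
    tot[, c("enumerated", "sa", "constrained", "csa")],
    dplyr::everything(), names_to = "stage", values_to = "count")
  df$stage <- factor(df$stage, levels = c("enumerated", "sa", "constrained",
                                          "csa"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), vjust = -0.4) +
    ggplot2::labs(x = NULL, y = "candidate sites") +
    ggplot2::theme_minimal()
}

#' Plot an alanine-hexapeptide scan
#'
#' Binding-energy loss per CDR window, selected windows highlighted.
#'
#' @param object A `flap_scan` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.flap_scan <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$name <- factor(df$name, levels = df$name)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$name, y = .data$loss,
                                   fill = .data$selected)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "magenta3"),
                               name = "selected") +
    ggplot2::labs(x = "CDR hexapeptide window",
                  y = "binding-energy loss on A6 replacement") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a fluctuation profile
#'
#' Per-residue mean heavy-atom RMSF along the chain.
#'
#' @param object A per-atom RMSF tibble (`flap_rmsf`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.flap_rmsf <- function(object, ...) {
  df <- object %>%
    dplyr::group_by(.data$chain, .data$resno) %>%
    dplyr::summarise(rmsf = mean(.data$rmsf), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$resno, y = .data$rmsf)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~chain, scales = "free_x") +
    ggplot2::labs(x = "residue", y = "RMSF (Å)") +
    ggplot2::theme_minimal()
}
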