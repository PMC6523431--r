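# ggplot2 views of the main result types.

#' Plot an LD decay curve
#'
#' @param curve An `ld_decay_curve` from [ld_decay()].
#' @param ... Unused.
#' @return A ggplot object: mean r-squared against pair distance in kb.
#' @export
plot_ld_decay <- function(curve, ...) {
  mid <- (curve$bin_start_bp + curve$bin_end_bp) / 2000
  ggplot2::ggplot(mutate(curve, dist_kb = mid),
                  ggplot2::aes(x = .data$dist_kb, y = .data$mean_r2)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "pair distance (kb)", y = expression(mean ~ r^2),
                  title = "LD decay") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.ld_decay_curve <- function(object, ...) plot_ld_decay(object, ...)

#' Plot phenotypes of the three gradient pairs
#'
#' Boxplots of the high and low subpopulations at each nesting level,
#' showing the growing contrast.
#'
#' @param series A `gradient_pairs` object.
#' @param ph The phenotype table it was built from.
#' @return A ggplot object.
#' @export
plot_gradient_pairs <- function(series, ph) {
  y <- setNames(ph[[series$trait]], ph$sample_id)
  df <- mutate(series$membership, phenotype = unname(y[.data$sample_id]),
               level = factor(.data$level))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$level, y = .data$phenotype,
                                   fill = .data$side)) +
    ggplot2::geom_boxplot(position = ggplot2::position_dodge()) +
    ggplot2::labs(x = "population pair", y = series$trait,
                  title = sprintf("Phenotypic gradient pairs: %s", series$trait)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.gradient_pairs <- function(object, ph, ...) {
  plot_gradient_pairs(object, ph)
}

#' Manhattan-style plot of a genome scan
#'
#' @param scan A tibble with `chromosome`, `position_bp` and a statistic
#'   column.
#' @param statistic Name of the statistic column to plot.
#' @param highlight Optional marker ids to colour (e.g. called
#'   signatures).
#' @return A ggplot object.
#' @export
plot_scan <- function(scan, statistic, highlight = NULL) {
  stopifnot(statistic %in% names(scan))
  df <- scan %>%
    arrange(chrom_order(.data$chromosome), .data$position_bp) %>%
    group_by(.data$chromosome) %>%
    mutate(pos_mb = .data$position_bp / 1e6) %>%
    ungroup() %>%
    mutate(called = if (is.null(highlight)) FALSE else
             .data$marker_id %in% highlight)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos_mb,
                                   y = .data[[statistic]],
                                   colour = .data$called)) +
    ggplot2::geom_point(size = 0.4, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "red")) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chromosome),
                        scales = "free_x", space = "free_x", switch = "x") +
    ggplot2::labs(x = "position (Mb)", y = statistic) +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.spacing.x = ggplot2::unit(0.1, "lines"),
                   axis.text.x = ggplot2::element_blank())
}

#' @exportS3Method ggplot2::autoplot
autoplot.window_score_table <- function(object, ...) {
  plot_scan(mutate(object, position_bp = (object$start_bp + object$end_bp) / 2,
                   marker_id = NA_character_),
            "mean_abs_ihs")
}
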