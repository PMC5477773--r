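# ggplot2 views of each result type.

#' Plot growth curves before and after evolution
#'
#' @param curves Curve tibble (`time_h`, `od`, `strain`, `status`).
#' @param log_od Plot OD on a log scale.
#' @return A ggplot object: one panel per strain, wild type vs evolved.
#' @export
plot_growth_curves <- function(curves, log_od = FALSE) {
  check_data_frame(curves, "curves", c("time_h", "od", "strain", "status"))
  curves <- as_tibble(curves)
  if (!"replicate" %in% names(curves)) curves$replicate <- 1L
  p <- ggplot2::ggplot(curves,
                       ggplot2::aes(x = .data$time_h, y = .data$od,
                                    colour = .data$status,
                                    group = interaction(.data$status,
                                                        .data$replicate))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$strain)) +
    ggplot2::labs(x = "time (h)", y = "OD600", colour = NULL) +
    ggplot2::theme_minimal()
  if (log_od) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot group-level expression summaries
#'
#' Wild-type vs evolved mean log2 xylulose/glucose ratio per gene group, with
#' standard-error bars across strains.
#'
#' @param summaries Output of [group_summary()].
#' @return A ggplot object.
#' @export
plot_group_summary <- function(summaries) {
  check_data_frame(summaries, "summaries", c("set", "status", "mean", "se"))
  wide <- tidyr::pivot_wider(summaries, id_cols = "set",
                             names_from = "status",
                             values_from = c("mean", "se"))
  ggplot2::ggplot(wide, ggplot2::aes(x = .data$mean_wt,
                                     y = .data$mean_evolved,
                                     label = .data$set)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_evolved - .data$se_evolved,
                                        ymax = .data$mean_evolved + .data$se_evolved),
                           width = 0, colour = "grey40") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$mean_wt - .data$se_wt,
                                         xmax = .data$mean_wt + .data$se_wt),
                            height = 0, colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(vjust = -0.8, size = 3) +
    ggplot2::labs(x = "wild type mean log2(xylulose/glucose)",
                  y = "evolved mean log2(xylulose/glucose)") +
    ggplot2::theme_minimal()
}

#' Plot expression change against growth improvement
#'
#' Scatter of per-strain group expression change (evolved/wild type, log2)
#' against effective-growth-rate fold, one colour per gene group, with the
#' fitted correlation line.
#'
#' @param x An `evo_correlation` object or a strain-change record tibble.
#' @return A ggplot object.
#' @export
plot_change_vs_growth <- function(x) {
  records <- if (inherits(x, "evo_correlation")) x$records else x
  check_data_frame(records, "records",
                   c("expression_change", "growth_improvement"))
  if (!"group" %in% names(records)) records$group <- "group"
  ggplot2::ggplot(records,
                  ggplot2::aes(x = .data$growth_improvement,
                               y = .data$expression_change,
                               colour = .data$group)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "effective growth rate fold (evolved / wt)",
                  y = "group expression change, log2(evolved / wt)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot evo_correlation
#' @export
autoplot.evo_correlation <- function(object, ...) {
  plot_change_vs_growth(object)
}

#' Plot group-vs-group expression coordinates
#'
#' Each population (strain x status) is placed in the plane of two gene
#' groups' mean log2 xylulose/glucose ratios; the arrow marks the average
#' displacement acquired during evolution.
#'
#' @param coords Output of [group_vs_group_coordinates()].
#' @return A ggplot object.
#' @export
plot_group_scatter <- function(coords) {
  cols <- grep("^mean_", names(coords), value = TRUE)
  stopifnot(length(cols) == 2L)
  disp <- attr(coords, "displacement")
  centres <- coords |>
    dplyr::group_by(.data$status) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(cols), mean),
                     .groups = "drop")
  p <- ggplot2::ggplot(coords,
                       ggplot2::aes(x = .data[[cols[1]]],
                                    y = .data[[cols[2]]],
                                    colour = .data$status)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = paste(sub("^mean_", "", cols[1]),
                            "mean log2(xylulose/glucose)"),
                  y = paste(sub("^mean_", "", cols[2]),
                            "mean log2(xylulose/glucose)"),
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(disp) && !anyNA(disp$displacement) &&
      all(c("wt", "evolved") %in% centres$status)) {
    wt_c <- centres[centres$status == "wt", cols]
    ev_c <- centres[centres$status == "evolved", cols]
    p <- p + ggplot2::annotate(
      "segment",
      x = wt_c[[1]], y = wt_c[[2]], xend = ev_c[[1]], yend = ev_c[[2]],
      colour = "red",
      arrow = grid::arrow(length = grid::unit(0.12, "inches"))
    )
  }
  p
}
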