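# ggplot2 helpers for the derived tables.

#' Plot the distribution of attributes used in working memory
#'
#' @param wm Output of [wm_usage_summary()].
#' @param by Condition column mapped to fill.
#' @return A ggplot object.
#' @export
plot_wm_distribution <- function(wm, by = "distraction") {
  cell <- wm |>
    dplyr::summarise(p = mean(.data$p_attributes),
                     .by = dplyr::all_of(c("attributes", by,
                                           intersect("movement_effort", names(wm)))))
  p <- ggplot2::ggplot(cell, ggplot2::aes(
    x = factor(.data$attributes), y = 100 * .data$p, fill = .data[[by]]
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "Attributes used in WM", y = "Sequences (%)",
                  fill = by)
  if ("movement_effort" %in% names(cell) && by != "movement_effort") {
    p <- p + ggplot2::facet_wrap(~movement_effort)
  }
  p
}

#' Plot memory-reliance probabilities per decision
#'
#' @param tbl Output of [p_memory_table()].
#' @param by Condition column mapped to colour.
#' @return A ggplot object.
#' @export
plot_p_memory <- function(tbl, by = "distraction") {
  ggplot2::ggplot(tbl, ggplot2::aes(
    x = interaction(.data$position, .data$kind, sep = "\n"),
    y = .data$p_memory, colour = .data[[by]], group = .data[[by]]
  )) +
    ggplot2::geom_point(size = 2, position = ggplot2::position_dodge(0.3)) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Decision (position within sequence)",
                  y = "P(use memory)", colour = by)
}

#' Plot identity/location error rates by sequence position
#'
#' @param tbl Output of [error_rate_table()].
#' @param by Condition column mapped to fill.
#' @return A ggplot object.
#' @export
plot_error_rates <- function(tbl, by = "distraction") {
  slot_order <- c("first_pickup", "first_placement",
                  "second_pickup", "second_placement")
  tbl$position_slot <- factor(tbl$position_slot, levels = slot_order)
  ggplot2::ggplot(tbl, ggplot2::aes(
    x = .data$position_slot, y = .data$error_rate_pct, fill = .data[[by]]
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~kind, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "Errors (%)", fill = by)
}

#' Plot a condition-level summary with SEM error bars
#'
#' @param tbl Output of [condition_summary()].
#' @param x Condition column on the x axis.
#' @param fill Optional second condition column.
#' @return A ggplot object.
#' @export
plot_condition_summary <- function(tbl, x = "distraction",
                                   fill = "movement_effort") {
  aes <- if (fill %in% names(tbl)) {
    ggplot2::aes(x = .data[[x]], y = .data$grand_mean, fill = .data[[fill]])
  } else {
    ggplot2::aes(x = .data[[x]], y = .data$grand_mean)
  }
  ggplot2::ggplot(tbl, aes) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$grand_mean - .data$sem,
                   ymax = .data$grand_mean + .data$sem),
      position = ggplot2::position_dodge(0.9), width = 0.2
    ) +
    ggplot2::labs(y = "Mean (participant means) ± SEM")
}

#' Overview plot of a pipeline result
#'
#' @param object A `copy_task_analysis`.
#' @param ... Unused.
#' @return A ggplot object: the working-memory attribute distribution.
#' @method autoplot copy_task_analysis
#' @export
autoplot.copy_task_analysis <- function(object, ...) {
  wm <- wm_usage_summary(object$sequences, object$meta)
  plot_wm_distribution(wm)
}
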