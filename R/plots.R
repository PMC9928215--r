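#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Box plots of RMSE improvement by joint and method
#'
#' One box per (joint, method) within each mode: the distribution over
#' subjects and target tasks of the improvement (benchmark RMSE minus
#' individualized RMSE, degrees). The dashed line at zero separates
#' improvement from degradation.
#'
#' @param object An `ikc_records` tibble from [evaluate_mode()] or
#'   [evaluate_all()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ikc_records <- function(object, ...) {
  df <- dplyr::mutate(object,
    joint = factor(.data$joint, levels = gait_joints),
    mode = factor(.data$mode, levels = gait_modes)
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$joint, y = .data$improvement_deg, fill = .data$method
  )) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_boxplot(outlier.size = 0.6, position = ggplot2::position_dodge(0.8)) +
    ggplot2::facet_wrap(ggplot2::vars(.data$mode), scales = "free_y") +
    ggplot2::labs(
      x = NULL, y = "RMSE improvement (deg)", fill = "Individualization",
      title = "Improvement over the non-individualized population average"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.ikc_records
#' @param records An `ikc_records` tibble.
#' @export
plot_improvement <- function(records, ...) {
  autoplot.ikc_records(records, ...)
}

#' Plot individual kinematic contributions across tasks
#'
#' Draws one IKC curve per task for a chosen subject, faceted by joint and
#' mode, so the within-mode persistence of a subject's deviation pattern is
#' visible directly.
#'
#' @param object An `ikc_curves` tibble from [compute_ikc()].
#' @param subject Subject to display (default: first present).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ikc_curves <- function(object, subject = NULL, ...) {
  subject <- subject %||% sort(unique(object$subject))[1]
  df <- object[object$subject == subject, , drop = FALSE] %>%
    dplyr::mutate(
      task = paste0(
        ifelse(is.na(.data$speed_mps), "", paste0(.data$speed_mps, " m/s ")),
        .data$incline_deg, "°"
      ),
      joint = factor(.data$joint, levels = gait_joints),
      mode = factor(.data$mode, levels = gait_modes)
    )
  ggplot2::ggplot(df, ggplot2::aes(
    x = 100 * (.data$phase_index - 1) / max(.data$phase_index),
    y = .data$ikc_deg, group = .data$task, colour = .data$task
  )) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$mode), cols = ggplot2::vars(.data$joint)
    ) +
    ggplot2::labs(
      x = "Gait cycle (%)", y = "IKC (deg)", colour = "Task",
      title = paste("Individual kinematic contributions -", subject)
    ) +
    ggplot2::theme_minimal()
}
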