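#' Plot a detection evaluation
#'
#' Bar chart of per-class AP, F1 and FNR with the class means overlaid
#' as dashed lines.
#'
#' @param object A `detection_eval` from [evaluate_detections()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot detection_eval
#' @export
autoplot.detection_eval <- function(object, ...) {
  long <- object$per_class |>
    dplyr::select("class", "ap", "f1", "fnr") |>
    tidyr::pivot_longer(c("ap", "f1", "fnr"),
      names_to = "metric", values_to = "value"
    ) |>
    dplyr::mutate(metric = toupper(.data$metric))
  means <- tibble::tibble(
    metric = c("AP", "F1", "FNR"),
    value = c(object$means$map, object$means$mf1, object$means$mfnr)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$class, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(
      data = means, ggplot2::aes(yintercept = .data$value),
      linetype = "dashed"
    ) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = NULL, y = "score",
      title = sprintf("Detection metrics (IoU ≥ %.2f)", object$iou_threshold),
      subtitle = "dashed line: unweighted class mean"
    ) +
    ggplot2::theme_minimal()
}

#' Plot metric confidence intervals
#'
#' Point estimates with BCa interval bars, one panel per metric — the
#' standard visual for judging significance by interval overlap when
#' comparing detectors and annotators. Bind the `metric_ci` tibbles of
#' several systems (adding a `system` column) before plotting to compare
#' them.
#'
#' @param object A `metric_ci` tibble from [evaluate_with_ci()],
#'   optionally with an extra `system` column.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot metric_ci
#' @export
autoplot.metric_ci <- function(object, ...) {
  df <- tibble::as_tibble(object)
  if (!"system" %in% names(df)) df$system <- "system"
  df$metric <- toupper(gsub("^m", "m", df$metric))
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$system, y = .data$point, color = .data$class)
  ) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$low, ymax = .data$high),
      position = ggplot2::position_dodge(width = 0.5)
    ) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = NULL, y = "score",
      title = sprintf(
        "%.0f%% BCa bootstrap confidence intervals",
        100 * df$level[1]
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot raw annotations and their fused consensus on one image
#'
#' Draws each annotator's boxes as thin colored rectangles and the
#' consensus boxes as thick black rectangles, in image coordinates
#' (y axis flipped, origin top-left).
#'
#' @param annotations Annotation tibble (one or more annotators).
#' @param consensus Consensus tibble from [fuse_annotations()]
#'   (optional).
#' @param image Which `image_id` to draw; defaults to the first.
#' @return A ggplot object.
#' @export
plot_consensus <- function(annotations, consensus = NULL, image = NULL) {
  image <- image %||% annotations$image_id[1]
  ann <- dplyr::filter(annotations, .data$image_id == image)
  p <- ggplot2::ggplot() +
    ggplot2::geom_rect(
      data = ann,
      ggplot2::aes(
        xmin = .data$xmin, xmax = .data$xmax,
        ymin = .data$ymin, ymax = .data$ymax,
        color = .data$annotator_id
      ),
      fill = NA, linewidth = 0.4
    )
  if (!is.null(consensus)) {
    cons <- dplyr::filter(consensus, .data$image_id == image)
    p <- p + ggplot2::geom_rect(
      data = cons,
      ggplot2::aes(
        xmin = .data$xmin, xmax = .data$xmax,
        ymin = .data$ymin, ymax = .data$ymax
      ),
      fill = NA, color = "black", linewidth = 1
    ) +
      ggplot2::geom_text(
        data = cons,
        ggplot2::aes(
          x = (.data$xmin + .data$xmax) / 2, y = .data$ymin,
          label = .data$label
        ),
        vjust = -0.4, size = 3
      )
  }
  p +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = paste("Image", image), x = "x (px)", y = "y (px)",
      color = "annotator"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a per-class precision-recall curve
#'
#' @param eval A `detection_eval` from [evaluate_detections()].
#' @param class Class to plot.
#' @return A ggplot object.
#' @export
plot_pr_curve <- function(eval, class) {
  det <- eval$match$det
  d <- det[det$label == class, , drop = FALSE]
  n_gt <- sum(eval$match$gt_counts$n_gt[eval$match$gt_counts$label == class])
  curve <- pr_curve(d$tp, d$confidence, n_gt)
  ap <- eval$per_class$ap[eval$per_class$class == class]
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      title = sprintf("Precision-recall: %s (AP = %.3f)", class, ap),
      x = "recall", y = "precision"
    ) +
    ggplot2::theme_minimal()
}
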