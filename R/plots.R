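## ggplot2 visualizations for the result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a synthetic scene with its ground-truth boxes
#'
#' @param object a scene from [generate_scene()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.ud_scene <- function(object, ...) {
  S <- dim(object$image)[2]
  ras <- aperm(object$image, c(2, 3, 1))
  boxes <- labels_to_boxes(object$annotations, S)
  boxes$class_name <- CLASS_NAMES[boxes$class_id + 1L]
  ggplot2::ggplot() +
    ggplot2::annotation_raster(ras, xmin = 0, xmax = S, ymin = -S, ymax = 0) +
    ggplot2::geom_rect(
      data = boxes,
      ggplot2::aes(xmin = .data$x1, xmax = .data$x2, ymin = -.data$y2,
                   ymax = -.data$y1, colour = .data$class_name),
      fill = NA, linewidth = 0.5) +
    ggplot2::coord_fixed(xlim = c(0, S), ylim = c(-S, 0), expand = FALSE) +
    ggplot2::labs(colour = "class", x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' Plot per-class precision-recall curves of an evaluation
#'
#' @param object an evaluation summary from [map_summary()].
#' @param ... unused.
#' @export
autoplot.ud_eval_summary <- function(object, ...) {
  ggplot2::ggplot(object$curves,
                  ggplot2::aes(x = .data$recall, y = .data$precision,
                               colour = .data$class_name)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "recall", y = "precision", colour = "class",
                  title = sprintf("mAP@0.5 = %.3f", object$map50)) +
    ggplot2::theme_minimal()
}

#' Plot the training loss curve
#'
#' @param object a report from [train_demo()].
#' @param ... unused.
#' @export
autoplot.ud_train_report <- function(object, ...) {
  ggplot2::ggplot(object$losses, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "mean loss",
                  title = sprintf("train-set mAP@0.5 = %.3f", object$map50)) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
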