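# ggplot2 visualisations for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_rect annotation_raster coord_fixed labs theme_minimal
NULL

#' @export
ggplot2::autoplot

scene_raster <- function(image) {
  grDevices::rgb(image[, , 1], image[, , 2], image[, , 3])
}

#' Plot a synthetic canopy scene with its ground truth
#'
#' @param object a `canopy_scene`.
#' @param boxes draw the ground-truth spike boxes?
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot canopy_scene
#' @export
autoplot.canopy_scene <- function(object, boxes = TRUE, ...) {
  d <- dim(object$image)
  rast <- matrix(scene_raster(object$image), d[1], d[2])
  p <- ggplot() +
    annotation_raster(rast, xmin = 0, xmax = d[2], ymin = -d[1], ymax = 0) +
    coord_fixed(xlim = c(0, d[2]), ylim = c(-d[1], 0), expand = FALSE) +
    labs(x = "x (px)", y = "y (px)",
         title = sprintf("synthetic scene: %d spikes", object$true_count)) +
    theme_minimal()
  if (boxes && nrow(object$spike_boxes)) {
    b <- object$spike_boxes
    p <- p + geom_rect(data = b,
                       aes(xmin = .data$xmin, xmax = .data$xmax,
                           ymin = -.data$ymax, ymax = -.data$ymin),
                       fill = NA, colour = "red", linewidth = 0.3)
  }
  p
}

#' Precision-recall curve of an AP evaluation
#'
#' @param object an `ap_result` from [average_precision()].
#' @param ... unused.
#' @method autoplot ap_result
#' @export
autoplot.ap_result <- function(object, ...) {
  ggplot(object$pr_curve, aes(.data$recall, .data$precision)) +
    geom_line(colour = "steelblue") + geom_point(size = 0.8) +
    labs(title = sprintf("AP@%.2f = %.3f", object$iou_thresh, object$ap),
         x = "recall", y = "precision") +
    theme_minimal()
}

#' Trait importances of a yield model
#'
#' @param object a `yield_model`.
#' @param ... unused.
#' @method autoplot yield_model
#' @export
autoplot.yield_model <- function(object, ...) {
  imp <- feature_importance(object)
  imp$trait <- stats::reorder(imp$trait, imp$importance)
  ggplot(imp, aes(.data$importance, .data$trait)) +
    geom_col(fill = "darkgreen") +
    labs(title = "normalized gain importance", x = "share of gain",
         y = NULL) +
    theme_minimal()
}
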