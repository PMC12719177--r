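# ggplot2 displays for heatmaps, ROC curves and scenes.

#' Plot a conductivity heatmap
#'
#' Tile map of per-location mean Rp; darker tiles (lower Rp) indicate higher
#' local conductivity, i.e. more lesion-like tissue.
#'
#' @param object An `ecd_heatmap`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.ecd_heatmap <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$col, y = .data$row, fill = .data$mean_rp_kohm)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = .data$location_id), size = 3) +
    ggplot2::scale_y_reverse(breaks = NULL) +
    ggplot2::scale_x_continuous(breaks = NULL) +
    ggplot2::scale_fill_viridis_c(name = "Rp (kOhm)") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = NULL, y = NULL,
      title = sprintf("Mean Rp per scan location (%s)", attr(object, "orientation"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot the ROC curve of an evaluation result
#'
#' @param object An `ecd_eval`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.ecd_eval <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", color = "grey60") +
    ggplot2::geom_step(linewidth = 0.8, color = "#2166ac") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("ROC (AUC = %.3f)", object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Top view of a scene's conductivity
#'
#' Shows the top voxel layer's conductivity with the scan points overlaid —
#' a quick check of what the sensor will see.
#'
#' @param scene An `ecd_scene`.
#' @return A ggplot.
#' @export
plot_scene_top <- function(scene) {
  stopifnot(inherits(scene, "ecd_scene"))
  top <- dplyr::filter(scene, .data$depth <= min(.data$depth) + 1e-9)
  sp <- scene_scan_points(scene)
  ggplot2::ggplot(tibble::as_tibble(top),
                  ggplot2::aes(x = .data$x * 100, y = .data$y * 100)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$sigma)) +
    ggplot2::geom_point(data = sp, ggplot2::aes(x = .data$x * 100, y = .data$y * 100),
                        shape = 4, size = 3, color = "white") +
    ggplot2::scale_fill_viridis_c(name = "sigma (S/m)", option = "magma") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (cm)", y = "y (cm)",
                  title = sprintf("Scene top layer: %s", scene_meta(scene)$type)) +
    ggplot2::theme_minimal()
}
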