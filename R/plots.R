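#' Plot Dice against binarization threshold
#'
#' Mean voxel-wise Dice over positive samples per sweep threshold, the curve
#' used to pick the operating threshold.
#'
#' @param records Metric records from [evaluate_sample()] or
#'   [evaluate_cohort()].
#' @return A ggplot object.
#' @export
plot_threshold_sweep <- function(records) {
  summ <- records |>
    dplyr::filter(.data$gt_positive) |>
    dplyr::group_by(.data$threshold) |>
    dplyr::summarise(mean_dice = mean(.data$dice, na.rm = TRUE),
                     .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$threshold, y = .data$mean_dice)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "probability threshold", y = "mean voxel-wise Dice (%)",
                  title = "Threshold sweep (positive samples)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a detection-threshold sensitivity analysis
#'
#' Patient-wise recall and precision as the true-positive Dice threshold is
#' made stricter.
#'
#' @param object A `periseg_sensitivity` tibble from
#'   [sensitivity_analysis()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.periseg_sensitivity <- function(object, ...) {
  long <- object |>
    dplyr::select("dice_threshold_pct", "recall", "precision") |>
    tidyr::pivot_longer(c("recall", "precision"), names_to = "metric",
                        values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$dice_threshold_pct,
                                     y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "TP Dice threshold (%)", y = "metric (%)",
                  title = "Detection-threshold sensitivity") +
    ggplot2::theme_minimal()
}

#' Plot an axial slice of a volume with optional mask overlays
#'
#' @param vol A `volume_grid` (or mask/probability map).
#' @param slice Axial slice index (defaults to the middle slice).
#' @param masks Optional named list of `binary_mask` overlays.
#' @return A ggplot object.
#' @export
plot_axial_slice <- function(vol, slice = NULL, masks = NULL) {
  stopifnot(inherits(vol, "volume_grid"))
  d <- dim(vol$values)
  if (is.null(slice)) slice <- ceiling(d[3] / 2)
  df <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]))
  df$value <- as.vector(vol$values[, , slice])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (!is.null(masks)) {
    for (nm in names(masks)) {
      m <- masks[[nm]]$values[, , slice]
      if (!any(m)) next
      idx <- which(m, arr.ind = TRUE)
      md <- data.frame(x = idx[, 1], y = idx[, 2], structure = nm)
      p <- p + ggplot2::geom_tile(
        data = md,
        ggplot2::aes(x = .data$x, y = .data$y, colour = .data$structure),
        fill = NA, inherit.aes = FALSE, linewidth = 0.1)
    }
  }
  p
}
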