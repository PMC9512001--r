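#' Diagnostic plot of the measurement pipeline
#'
#' Two stacked panels in the style of the standard pipeline summary figure:
#' the meridian intensity profile with the assigned zone boundaries, and the
#' absolute first derivative with all detected peaks (accepted boundaries
#' filled).
#'
#' @param measurement An `ok_measurement` from [measure_pattern()].
#' @param path Optional PNG path; when given the plot is written there
#'   instead of the active device.
#' @return Invisibly, `measurement`.
#' @export
plot_pipeline <- function(measurement, path = NULL) {
  stopifnot(inherits(measurement, "ok_measurement"))
  if (!is.null(path)) {
    grDevices::png(path, width = 900, height = 700)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op), add = TRUE)

  prof <- as.numeric(measurement$profile)
  graphics::plot(seq_along(prof) - 1L, prof, type = "l",
                 xlab = "column (px)", ylab = "intensity",
                 main = paste0(measurement$image_id, ": meridian profile"))
  graphics::abline(v = measurement$edges$x, col = "forestgreen", lty = 2)

  der <- as.numeric(measurement$derivative)
  graphics::plot(seq_along(der) - 1L, der, type = "l",
                 xlab = "column (px)", ylab = "|dI/dx|",
                 main = "absolute first derivative")
  graphics::points(measurement$peaks$positions, measurement$peaks$magnitudes,
                   pch = 1, col = "grey40")
  sel <- measurement$peaks$positions %in% measurement$edges$x
  graphics::points(measurement$peaks$positions[sel],
                   measurement$peaks$magnitudes[sel],
                   pch = 19, col = "forestgreen")
  invisible(measurement)
}

#' Bland-Altman plot for one agreement comparison
#'
#' Differences against pair means, with a solid line at the mean difference,
#' dashed lines at the 95% limits of agreement, and shaded confidence bands
#' around each limit.
#'
#' @param summary An `agreement_summary` from [paired_summary()].
#' @param ci_mode CI mode passed to [loa_confidence_interval()].
#' @param title Plot title.
#' @return A ggplot object.
#' @export
bland_altman_plot <- function(summary, ci_mode = "approximate",
                              title = NULL) {
  stopifnot(inherits(summary, "agreement_summary"))
  ci <- loa_confidence_interval(summary, mode = ci_mode)
  df <- data.frame(mean = summary$means, diff = summary$differences)
  bands <- data.frame(
    ymin = c(ci$loa_low["lower"], ci$loa_high["lower"]),
    ymax = c(ci$loa_low["upper"], ci$loa_high["upper"]))
  if (is.null(title)) {
    title <- sprintf("%s - %s", summary$labels[1L], summary$labels[2L])
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_rect(data = bands,
                       ggplot2::aes(ymin = .data$ymin, ymax = .data$ymax),
                       xmin = -Inf, xmax = Inf, inherit.aes = FALSE,
                       fill = "grey80", alpha = 0.5) +
    ggplot2::geom_hline(yintercept = summary$mean_diff, linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = c(summary$loa_low, summary$loa_high),
                        linetype = "dashed") +
    ggplot2::geom_point(shape = 1) +
    ggplot2::labs(x = "mean of pair (mm)", y = "difference (mm)",
                  title = title,
                  subtitle = sprintf("mean %.2f, LoA [%.2f, %.2f] mm",
                                     summary$mean_diff, summary$loa_low,
                                     summary$loa_high)) +
    ggplot2::theme_minimal()
}
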