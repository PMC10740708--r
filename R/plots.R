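#' Heatmap of the two class densities with the DTC overlaid
#'
#' Renders the two bivariate Gaussian densities (their pointwise maximum, so
#' both clusters are visible) as a top-view heatmap over the boundary's
#' bounding box, with the decision threshold curve drawn in white. Axes are in
#' log-concentration units. For a boundary-free problem the heatmap is drawn
#' without a curve and annotated with the dominant hypothesis.
#'
#' @param problem a two-dimensional [decision_problem()].
#' @param boundary a `decision_boundary` from [trace_dtc()].
#' @param path output file (extension selects the device, e.g. `.png`,
#'   `.svg`); `NULL` returns the ggplot object without writing.
#' @param grid_n heatmap resolution per axis (default 200).
#' @return The ggplot object, invisibly when written to `path`.
#' @export
plot_dtc_heatmap <- function(problem, boundary, path = NULL, grid_n = 200L) {
  if (problem$dim != 2L) stop("heatmap plotting requires a two-dimensional problem")
  bbox <- boundary$bbox %||% default_bbox(problem)
  gx <- seq(bbox[1], bbox[2], length.out = grid_n)
  gy <- seq(bbox[3], bbox[4], length.out = grid_n)
  pts <- cbind(rep(gx, times = grid_n), rep(gy, each = grid_n))
  dens <- pmax(exp(log_pdf(problem$h0, pts)) * problem$prior0,
               exp(log_pdf(problem$h1, pts)) * problem$prior1)
  df <- data.frame(x = pts[, 1], y = pts[, 2], density = dens)

  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$density)) +
    ggplot2::scale_fill_viridis_c(option = "magma") +
    ggplot2::coord_cartesian(expand = FALSE) +
    ggplot2::labs(x = "ln(output 1 concentration)",
                  y = "ln(output 2 concentration)",
                  fill = "weighted\ndensity") +
    ggplot2::theme_minimal()
  if (length(boundary$curves) > 0L) {
    for (i in seq_along(boundary$curves)) {
      p <- p + ggplot2::geom_path(data = boundary$curves[[i]],
                                  ggplot2::aes(x = .data$x, y = .data$y),
                                  color = "white", linewidth = 0.9)
    }
  } else {
    p <- p + ggplot2::annotate("label", x = mean(bbox[1:2]), y = bbox[4] -
                                 0.06 * diff(bbox[3:4]),
                               label = paste0("boundary-free: ",
                                              boundary$dominant,
                                              " decided everywhere"))
  }
  if (is.null(path)) return(p)
  ggplot2::ggsave(path, p, width = 6, height = 5, dpi = 150)
  invisible(p)
}
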