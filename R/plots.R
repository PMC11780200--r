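#' Heatmap of a landscape population surface
#'
#' Population size per landscape as a colour surface over the habitat
#' quantity (percent SNH cover) and habitat quality (Q1-Q20 flower
#' availability) axes.
#'
#' @param matrix A [build_population_matrix()] result.
#' @param path Optional output file; the extension picks the device
#'   (e.g. `.png`, `.svg`, `.pdf`).
#' @return The ggplot object, invisibly when written to file.
#' @export
plot_population_surface <- function(matrix, path = NULL) {
  stopifnot(inherits(matrix, "population_matrix"))
  long <- as_tibble(matrix)
  long$snh_f <- factor(long$snh_pct, levels = matrix$snh_pct)
  p <- ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$snh_f, y = .data$quality_level, fill = .data$population)
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "Population\n(individuals)") +
    ggplot2::scale_y_continuous(
      breaks = c(1, 5, 10, 15, 20),
      labels = function(b) paste0("Q", b)
    ) +
    ggplot2::labs(
      x = "Seminatural habitat cover (%)",
      y = "Habitat quality (flower availability)",
      title = sprintf(
        "Estimated %s population size per landscape (radius %g m)",
        matrix$taxon, matrix$radius_m
      )
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (is.null(path)) {
    return(p)
  }
  ggplot2::ggsave(path, p, width = 8, height = 5, dpi = 150)
  invisible(p)
}

#' Quality:quantity response-ratio curves
#'
#' The ratio of population gains (k quality steps vs one SNH step) against
#' SNH cover, one curve per quality level, with the break-even reference
#' line at 1 and threshold crossings marked.  Ratios above the line mean
#' improving quality beats adding habitat at that landscape configuration.
#'
#' @param result A [ratio_curve()] result.
#' @param path Optional output file (extension picks the device).
#' @return The ggplot object, invisibly when written to file.
#' @export
plot_ratio_curves <- function(result, path = NULL) {
  stopifnot(inherits(result, "tradeoff_result"))
  cur <- result$curve[!is.na(result$curve$ratio), ]
  if (nrow(cur) == 0) stop("no defined ratio values to plot", call. = FALSE)
  thr <- result$thresholds[!is.na(result$thresholds$threshold_snh_pct), ]
  p <- ggplot2::ggplot(
    cur,
    ggplot2::aes(
      x = .data$snh_pct, y = .data$ratio,
      group = .data$quality_level, colour = .data$quality_level
    )
  ) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::scale_colour_viridis_c(name = "Quality level") +
    ggplot2::labs(
      x = "Seminatural habitat cover (%)",
      y = sprintf("Quality:quantity response ratio (%d:1 steps)", result$step_ratio),
      title = sprintf(
        "%s: where improving habitat quality beats adding habitat",
        result$taxon
      )
    ) +
    ggplot2::theme_minimal()
  if (nrow(thr) > 0) {
    p <- p + ggplot2::geom_point(
      data = data.frame(
        snh_pct = thr$threshold_snh_pct, ratio = 1,
        quality_level = thr$quality_level
      ),
      shape = 4, size = 2
    )
  }
  if (is.null(path)) {
    return(p)
  }
  ggplot2::ggsave(path, p, width = 8, height = 5, dpi = 150)
  invisible(p)
}
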