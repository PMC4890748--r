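#' Chromosomal view of a binned track
#'
#' Draws the per-bin values along each chromosome (facets in genome order),
#' leaving gaps where bins are masked, and shades pericentromeric intervals
#' when a genome model is supplied.
#'
#' @param object A binned track (log2 ratio track, frequency profile, ...).
#' @param genome Optional [genome_model()] for pericentromere shading.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.binned_track <- function(object, genome = NULL, ...) {
  df <- tibble::as_tibble(object) %>%
    dplyr::mutate(mid = (.data$start + .data$end) / 2 / 1e6)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$value))
  if (!is.null(genome) && nrow(genome$pericentromere) > 0L) {
    peri <- genome$pericentromere %>%
      dplyr::mutate(xmin = .data$start / 1e6, xmax = .data$end / 1e6)
    p <- p + ggplot2::geom_rect(
      data = peri,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax),
      ymin = -Inf, ymax = Inf, fill = "grey85", inherit.aes = FALSE
    )
  }
  p +
    ggplot2::geom_line(na.rm = TRUE, linewidth = 0.3) +
    ggplot2::facet_wrap(~chrom, ncol = 1, strip.position = "right") +
    ggplot2::labs(x = "Position (Mb)", y = "Value") +
    ggplot2::theme_minimal()
}

#' Overlay a ploidy mixture fit on its histogram
#'
#' @param object A `ploidy_fit`.
#' @param hist The histogram the fit was computed from.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ploidy_fit <- function(object, hist, ...) {
  hist <- validate_histogram(hist)
  total <- sum(hist$count)
  width <- hist$upper - hist$lower
  x <- seq(min(hist$lower), max(hist$upper), length.out = 512)
  dens <- rowSums(vapply(seq_len(object$K), function(k) {
    object$weights[k] * stats::dnorm(x, object$peak_means[k], object$sigma[k])
  }, numeric(length(x))))
  curve <- tibble::tibble(x = x, y = dens * total * mean(width))
  ggplot2::ggplot() +
    ggplot2::geom_col(
      data = hist,
      ggplot2::aes(x = (.data$lower + .data$upper) / 2, y = .data$count),
      width = width, fill = "grey70"
    ) +
    ggplot2::geom_line(
      data = curve, ggplot2::aes(x = .data$x, y = .data$y),
      colour = "firebrick"
    ) +
    ggplot2::labs(x = "Fluorescence intensity (a.u.)", y = "Nuclei") +
    ggplot2::theme_minimal()
}

#' Boxplot of per-sample RPKM over a defined feature set
#'
#' @param summary Output of [set_summary()].
#' @param log_scale Plot RPKM on log10 axis (a pseudo-count of 0.1 is
#'   added).
#' @return A ggplot object.
#' @export
plot_set_rpkm <- function(summary, log_scale = TRUE) {
  values <- summary$values
  p <- ggplot2::ggplot(
    values,
    ggplot2::aes(x = .data$sample, y = .data$rpkm + if (log_scale) 0.1 else 0)
  ) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::labs(x = NULL, y = if (log_scale) "RPKM + 0.1" else "RPKM") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (log_scale) p <- p + ggplot2::scale_y_log10()
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
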