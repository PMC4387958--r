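#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an LD decay curve
#'
#' @param object An `ld_decay` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ld_decay <- function(object, ...) {
  cv <- object[object$n_pairs > 0, ]
  ggplot2::ggplot(cv, ggplot2::aes(x = .data$mean_dist_kb, y = .data$mean_r2)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_pairs)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "inter-site distance (kb)",
                  y = expression(mean ~ r^2), size = "pairs") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.ld_decay
#' @param curve An `ld_decay` tibble.
#' @export
plot_ld_decay <- function(curve, ...) autoplot.ld_decay(curve, ...)

#' Plot an XP-CLR scan track
#'
#' @param object An `xpclr_scan`.
#' @param regions Optional region table from [call_regions()], shaded.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.xpclr_scan <- function(object, regions = NULL, ...) {
  p <- ggplot2::ggplot(object$track,
                       ggplot2::aes(x = .data$pos / 1e6, y = .data$score)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "XP-CLR score",
                  title = paste("Test population:", object$test_pop)) +
    ggplot2::theme_minimal()
  if (!is.null(regions) && nrow(regions))
    p <- p + ggplot2::geom_rect(
      data = regions,
      ggplot2::aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6),
      ymin = -Inf, ymax = Inf, alpha = 0.2, fill = "tomato",
      inherit.aes = FALSE)
  p
}

#' Plot PCA sample scores
#'
#' @param object A `geno_pca`.
#' @param pop_map Optional population map for colouring.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.geno_pca <- function(object, pop_map = NULL, ...) {
  sc <- object$scores
  if (!is.null(pop_map))
    sc <- dplyr::left_join(sc, pop_map, by = "sample")
  aes <- if (!is.null(pop_map))
    ggplot2::aes(x = .data$PC1, y = .data$PC2, colour = .data$population)
  else ggplot2::aes(x = .data$PC1, y = .data$PC2)
  ggplot2::ggplot(sc, aes) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_frac[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_frac[2])) +
    ggplot2::theme_minimal()
}

#' Plot a minor-allele-frequency spectrum
#'
#' @param spectrum A `maf_spectrum`.
#' @return A ggplot.
#' @export
plot_maf_spectrum <- function(spectrum) {
  ggplot2::ggplot(spectrum$histogram,
                  ggplot2::aes(x = (.data$lo + .data$hi) / 2, y = .data$n)) +
    ggplot2::geom_col(width = 0.04) +
    ggplot2::labs(x = "minor allele frequency", y = "variants") +
    ggplot2::theme_minimal()
}
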