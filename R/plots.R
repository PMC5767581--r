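#' Plot a coherence spectrum
#'
#' Line plot of coherence against frequency with the beta band shaded.
#'
#' @param object A `cmc_coherence`.
#' @param band Band to shade (default 15-30 Hz); `NULL` for none.
#' @param xlim Frequency range shown.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cmc_coherence
#' @export
autoplot.cmc_coherence <- function(object, band = c(15, 30),
                                   xlim = c(0, 60), ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$freq, y = .data$coherence))
  if (!is.null(band)) {
    p <- p + ggplot2::annotate("rect", xmin = band[1], xmax = band[2],
                               ymin = -Inf, ymax = Inf, alpha = 0.12,
                               fill = "steelblue")
  }
  pr <- attr(object, "pair")
  p + ggplot2::geom_line() +
    ggplot2::coord_cartesian(xlim = xlim) +
    ggplot2::labs(x = "Frequency (Hz)", y = "Coherence",
                  title = paste0("CMC: ", pr[1], " ~ ", pr[2]),
                  subtitle = paste0("L = ", attr(object, "L"), " epochs, K = ",
                                    attr(object, "K"), " tapers")) +
    ggplot2::theme_minimal()
}

#' Plot a band-coherence topography
#'
#' Electrodes are shown in an azimuthal (polar) projection of the upper
#' head sphere, coloured by band-mean coherence; the peak electrode is
#' circled.
#'
#' @param object A `cmc_topography` carrying electrode positions.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cmc_topography
#' @export
autoplot.cmc_topography <- function(object, ...) {
  if (!all(c("x", "y", "z") %in% names(object))) {
    stop("topography has no electrode positions to plot", call. = FALSE)
  }
  df <- tibble::as_tibble(object)
  # azimuthal equidistant projection: radius ~ polar angle from vertex
  th <- acos(pmin(1, pmax(-1, df$z)))
  az <- atan2(df$y, df$x)
  df$px <- th * cos(az)
  df$py <- th * sin(az)
  pk <- df[df$electrode == attr(object, "peak_electrode"), ]
  b <- attr(object, "band")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$px, y = .data$py,
                                   colour = .data$coherence)) +
    ggplot2::geom_point(size = 4) +
    ggplot2::geom_point(data = pk, shape = 21, size = 6, stroke = 1.2,
                        colour = "black", fill = NA) +
    ggplot2::scale_colour_viridis_c(name = "CMC") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("Beta-band (%g-%g Hz) CMC topography",
                                  b[1], b[2]),
                  subtitle = paste("peak:", attr(object, "peak_electrode")),
                  x = NULL, y = NULL) +
    ggplot2::theme_void() +
    ggplot2::theme(plot.title = ggplot2::element_text(hjust = 0.5),
                   plot.subtitle = ggplot2::element_text(hjust = 0.5))
}

#' Plot a permutation test result
#'
#' Histogram of the null (random-partition) statistics with the observed
#' statistic marked.
#'
#' @param object A `cmc_permutation`.
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cmc_permutation
#' @export
autoplot.cmc_permutation <- function(object, bins = 50, ...) {
  df <- tibble::tibble(stat = object$null_stats)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stat)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey65", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$observed_stat,
                        colour = "firebrick", linewidth = 1) +
    ggplot2::labs(x = "Max cluster mass (null partitions)", y = "Count",
                  title = "Cluster-based permutation test",
                  subtitle = sprintf("observed = %.3f, Monte Carlo p = %.4f",
                                     object$observed_stat, object$p_mc)) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
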