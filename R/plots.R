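#' Plot an RT (or any bin) track along the genome
#'
#' @param track Bin-track tibble.
#' @param segments Optional segment tibble to overlay as step means.
#' @return A ggplot object, faceted by chromosome.
#' @export
plot_rt_track <- function(track, segments = NULL) {
  p <- ggplot2::ggplot(track[!is.na(track$value), ],
                       ggplot2::aes(x = (.data$start + .data$end) / 2e6,
                                    y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "grey30") +
    ggplot2::facet_wrap(~chrom, ncol = 1, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "log2(early / late)") +
    ggplot2::theme_minimal()
  if (!is.null(segments)) {
    p <- p + ggplot2::geom_segment(
      data = segments,
      ggplot2::aes(x = .data$start / 1e6, xend = .data$end / 1e6,
                   y = .data$mean, yend = .data$mean),
      colour = "firebrick", linewidth = 0.8
    )
  }
  p
}

#' Plot strand-bias metagene profiles per stratum
#'
#' Crick fraction against offset from the site center, one curve per
#' stratum; 0.5 (no directional bias) is marked.
#'
#' @param profile Tibble from [strand_bias_metagene()].
#' @return A ggplot object.
#' @export
plot_strand_bias <- function(profile) {
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = .data$offset / 1e3,
                               y = .data$crick_fraction,
                               colour = factor(.data$stratum))) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "offset from site (kb)", y = "Crick fraction",
                  colour = "stratum") +
    ggplot2::theme_minimal()
}

#' Plot the feature weights of an elastic-net RT fit
#'
#' @param object An `rt_enet_fit`.
#' @param ... Unused.
#' @return A ggplot bar chart of standardized weights, ordered by magnitude.
#' @export
autoplot.rt_enet_fit <- function(object, ...) {
  w <- tidy(object)
  w$feature <- factor(w$feature, levels = rev(w$feature))
  ggplot2::ggplot(w, ggplot2::aes(x = .data$weight, y = .data$feature)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey40") +
    ggplot2::labs(x = "parameter weight (standardized)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a mean metagene profile
#'
#' @param profile Tibble from [mean_profile()].
#' @return A ggplot object.
#' @export
plot_metagene_profile <- function(profile) {
  ggplot2::ggplot(profile[!is.na(profile$value), ],
                  ggplot2::aes(x = .data$offset / 1e3, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "offset (kb)", y = "mean signal") +
    ggplot2::theme_minimal()
}
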