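#' Plot a clade-discrimination profile
#'
#' Per-column discrimination scores along the alignment, with optional
#' shading of conserved regions and markers for candidate windows.
#'
#' @param profile A tibble from [discrimination_profile()].
#' @param regions Optional region map tibble (`region`, `start`, `end`) in
#'   reference coordinates; drawn as shaded bands.
#' @param cmap Optional `coord_map` (required to place `regions` when the
#'   profile spans gapped reference columns).
#' @return A ggplot object.
#' @export
plot_discrimination_profile <- function(profile, regions = NULL,
                                        cmap = NULL) {
  p <- ggplot2::ggplot(profile,
                       ggplot2::aes(x = .data$col, y = .data$score))
  if (!is.null(regions)) {
    cols <- if (!is.null(cmap)) {
      tibble(xmin = cmap$ref_to_col[regions$start],
             xmax = cmap$ref_to_col[regions$end],
             region = regions$region)
    } else {
      tibble(xmin = regions$start, xmax = regions$end,
             region = regions$region)
    }
    p <- p + ggplot2::geom_rect(
      data = cols, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = -Inf, ymax = Inf),
      fill = "grey90")
  }
  p +
    ggplot2::geom_col(width = 1, fill = "grey20") +
    ggplot2::labs(x = "alignment column",
                  y = "off-target rows differing from target consensus") +
    ggplot2::theme_classic()
}

#' Plot amplicon-length spectrum of simulated PCR hits
#'
#' Histogram of predicted amplicon lengths, split by total primer-template
#' mismatches. The in silico analogue of reading band patterns off a gel:
#' multi-banding and off-length products indicate non-specific priming.
#'
#' @param object A `pcr_hits` tibble from [simulate_pcr()].
#' @param binwidth Histogram bin width in bp.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pcr_hits
#' @export
autoplot.pcr_hits <- function(object, binwidth = 50, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$length_bp,
                                  fill = factor(.data$total_mm))) +
    ggplot2::geom_histogram(binwidth = binwidth, colour = "black",
                            boundary = 0) +
    ggplot2::labs(x = "predicted amplicon length (bp)",
                  y = "amplicons", fill = "total mismatches") +
    ggplot2::theme_classic()
}
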