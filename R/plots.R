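## ggplot2 graphics for scan results.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' LOD profile plot of a genome scan
#'
#' @param object A `cnimap_scan` from [genome_scan()].
#' @param threshold Optional genome-wide threshold to draw, on the LOD
#'   scale (convert an LR threshold with [lr_to_lod()]).
#' @param ... Unused.
#' @return A ggplot object: LOD against position, faceted by chromosome,
#'   with the peak marked.
#' @method autoplot cnimap_scan
#' @export
autoplot.cnimap_scan <- function(object, threshold = NULL, ...) {
  df <- tibble::as_tibble(object)
  pk <- attr(object, "peak")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$position_cM,
                                        y = .data$lod)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(data = pk, colour = "firebrick", size = 2) +
    ggplot2::labs(x = "position (cM)", y = "LOD") +
    ggplot2::theme_minimal()
  if (length(unique(df$chromosome)) > 1L) {
    p <- p + ggplot2::facet_grid(cols = ggplot2::vars(.data$chromosome),
                                 scales = "free_x", space = "free_x")
  }
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold,
                                 linetype = "dashed", colour = "firebrick")
  }
  p
}

#' @rdname autoplot.cnimap_scan
#' @param scan A `cnimap_scan`.
#' @export
plot_lod_profile <- function(scan, threshold = NULL) {
  autoplot(scan, threshold = threshold)
}
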