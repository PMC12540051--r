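# Reporting figures (ggplot2, Suggests).

.needGgplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
}

#' Bubble plot of enrichment calls
#'
#' One bubble per genus: size = baseline relative abundance at 0 h, colour =
#' mean enrichment factor, asterisk label on significantly enriched genera.
#'
#' @param calls data.frame from [callEnrichment()].
#' @return a ggplot object.
#' @export
plotEnrichmentBubbles <- function(calls) {
  .needGgplot()
  calls$label <- ifelse(calls$enriched, "*", "")
  ggplot2::ggplot(
    calls,
    ggplot2::aes(x = mean_ef, y = stats::reorder(genus, mean_ef))
  ) +
    ggplot2::geom_point(ggplot2::aes(size = baseline_ra,
                                     colour = mean_ef)) +
    ggplot2::geom_text(ggplot2::aes(label = label), vjust = -0.4) +
    ggplot2::scale_colour_gradient2(low = "steelblue", mid = "grey85",
                                    high = "firebrick", midpoint = 0) +
    ggplot2::labs(x = "mean enrichment factor", y = NULL,
                  size = "baseline RA (0 h)", colour = "EF") +
    ggplot2::theme_minimal()
}

#' PCoA ordination plot
#'
#' First two principal coordinates, coloured by a metadata column.
#'
#' @param ord list from [pcoaOrdination()].
#' @param meta data.frame of per-sample metadata (rows matching the
#'   ordination).
#' @param colour name of the metadata column to colour by.
#' @return a ggplot object.
#' @export
plotPcoa <- function(ord, meta, colour = "donor") {
  .needGgplot()
  if (ncol(ord$points) < 2)
    stop("fewer than two positive principal coordinates")
  df <- data.frame(
    PCo1 = ord$points[, 1], PCo2 = ord$points[, 2],
    colour = meta[[colour]]
  )
  pct <- round(100 * ord$rel_eig[1:2], 1)
  ggplot2::ggplot(df, ggplot2::aes(PCo1, PCo2,
                                   colour = colour)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(
      x = sprintf("PCo1 (%.1f%%)", pct[1]),
      y = sprintf("PCo2 (%.1f%%)", pct[2]),
      colour = colour
    ) +
    ggplot2::theme_minimal()
}
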