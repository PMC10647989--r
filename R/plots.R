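#' ISD chart
#'
#' The normalized chart: signed ISD (%) per isodose level, horizontal
#' acceptance lines at exactly +/-100% for every level, and a vertical
#' dashed divider at ISOmr separating the "Normal Tissue" region (at and
#' below ISOmr) from the "PTV" region (above). The per-level asymmetric raw
#' limits remain available through [plotRawTolerance()].
#'
#' @param curve an [IsdCurve-class].
#' @return a ggplot object.
#' @export
plotIsd <- function(curve) {
  stopifnot(is(curve, "IsdCurve"))
  e <- curve@entries
  y_top <- max(120, max(abs(e$isdPercent)) * 1.1)
  ggplot2::ggplot(e, ggplot2::aes(x = .data$level, y = .data$isdPercent)) +
    ggplot2::geom_hline(yintercept = c(-100, 100), colour = "red3") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_vline(xintercept = curve@isoMr, linetype = "dashed") +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$withinTolerance),
                        size = 2, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "steelblue4",
                                            `FALSE` = "red3")) +
    ggplot2::annotate("text", x = curve@isoMr, y = y_top,
                      label = " Normal Tissue | PTV ", size = 3,
                      hjust = 0.5, vjust = 0) +
    ggplot2::coord_cartesian(ylim = c(-y_top, y_top * 1.08)) +
    ggplot2::labs(x = "Isodose level (%)", y = "ISD (%)",
                  title = sprintf("Isodose surface differences (ISOmr %g%%)",
                                  curve@isoMr)) +
    ggplot2::theme_bw()
}

#' Raw (un-normalized) Bray-Curtis chart with asymmetric tolerance limits
#'
#' Plots the raw per-isodose Bray-Curtis dissimilarity together with its
#' per-level BC_ISOup and BC_ISOlow acceptance limits, before the
#' normalization that straightens the tolerance lines to +/-100%.
#'
#' @param curve an [IsdCurve-class].
#' @return a ggplot object.
#' @export
plotRawTolerance <- function(curve) {
  stopifnot(is(curve, "IsdCurve"))
  e <- curve@entries
  long <- rbind(
    data.frame(level = e$level, value = e$bc, series = "BC (eval vs ref)"),
    data.frame(level = e$level, value = e$bcUp, series = "BC_ISOup limit"),
    data.frame(level = e$level, value = e$bcLow, series = "BC_ISOlow limit"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$level, y = .data$value,
                                     colour = .data$series,
                                     linetype = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::scale_colour_manual(values = c("BC (eval vs ref)" = "black",
                                            "BC_ISOup limit" = "red3",
                                            "BC_ISOlow limit" = "steelblue4")) +
    ggplot2::labs(x = "Isodose level (%)", y = "Bray-Curtis dissimilarity",
                  colour = NULL, linetype = NULL,
                  title = "Raw isodose differences and tolerance limits") +
    ggplot2::theme_bw()
}
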