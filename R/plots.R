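#' Dot plot of network propagation results
#'
#' Stationary probability against betweenness centrality for the seeded DEG
#' nodes, colored by the sign of the log2 fold change, with key genes
#' labelled. Requires ggplot2.
#'
#' @param prop propagation result from [propagate_degs()].
#' @return a ggplot object.
#' @export
plot_propagation <- function(prop) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  d <- prop[prop$is_deg, , drop = FALSE]
  d$regulation <- ifelse(d$log2FC > 0, "up", "down")
  ggplot2::ggplot(d, ggplot2::aes(x = betweenness,
                                  y = probability,
                                  color = regulation)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_point(data = d[d$key, , drop = FALSE], shape = 1,
                        size = 3, color = "black") +
    ggplot2::scale_color_manual(values = c(up = "#B2182B", down = "#2166AC")) +
    ggplot2::labs(x = "betweenness centrality",
                  y = "stationary probability") +
    ggplot2::theme_minimal()
}

#' Volcano plot of a differential-expression table
#'
#' @param de DE result table from [nb_wald_test()].
#' @param alpha significance level used for coloring.
#' @return a ggplot object.
#' @export
plot_volcano <- function(de, alpha = 0.05) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  d <- de[is.finite(de$p), , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = log2FC,
                                  y = -log10(p),
                                  color = direction)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_color_manual(values = c(up = "#B2182B", down = "#2166AC",
                                           ns = "grey70")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p") +
    ggplot2::theme_minimal()
}

utils::globalVariables(c("betweenness", "probability", "regulation",
                         "log2FC", "p", "direction"))
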