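#' Ratio-intensity plot of a DEG table
#'
#' MA-style view of one contrast: log2 background-subtracted ratio against
#' log10 control signal, coloured by call direction.
#'
#' @param object A [call_degs()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot deg_table
#' @export
autoplot.deg_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df <- df[df$valid, , drop = FALSE]
  th <- attr(object, "thresholds")
  ggplot2::ggplot(df, ggplot2::aes(x = log10(.data$control_signal),
                                   y = log2(.data$ratio),
                                   colour = .data$direction)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = log2(c(th[["up"]], th[["down"]])),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::scale_colour_manual(values = c(up = "#c0392b", down = "#27ae60",
                                            none = "grey65")) +
    ggplot2::labs(title = paste("Contrast:", attr(object, "contrast")),
                  x = "log10 control signal",
                  y = "log2 ratio (background-subtracted)",
                  colour = "call")
}

#' Bar chart of exclusive Venn region sizes
#'
#' @param object A [venn_partition()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot deg_partition
#' @export
autoplot.deg_partition <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$region <- factor(df$region, levels = df$region)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region, y = .data$n,
                                   fill = factor(.data$degree))) +
    ggplot2::geom_col() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.4, size = 3) +
    ggplot2::labs(x = "membership signature", y = "identifiers in region",
                  fill = "sets") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Dendrogram with AU/BP support labels
#'
#' Draws the sample dendrogram with rectangular branches; internal nodes are
#' annotated `AU|BP` (percent), AU above the threshold highlighted.
#'
#' @param object A [multiscale_bootstrap()] result.
#' @param au_threshold Highlight AU values above this cut-off (default 0.95).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot supported_dendrogram
#' @export
autoplot.supported_dendrogram <- function(object, au_threshold = 0.95, ...) {
  merge <- object$merge
  height <- object$height
  ord <- object$order
  xleaf <- setNames(seq_along(ord), ord)   # leaf index -> x position
  nx <- numeric(nrow(merge))
  segs <- NULL
  xpos <- function(node) if (node < 0) xleaf[[as.character(-node)]] else nx[node]
  ypos <- function(node) if (node < 0) 0 else height[node]
  for (k in seq_len(nrow(merge))) {
    x1 <- xpos(merge[k, 1]); x2 <- xpos(merge[k, 2])
    y1 <- ypos(merge[k, 1]); y2 <- ypos(merge[k, 2])
    nx[k] <- (x1 + x2) / 2
    segs <- rbind(segs,
                  data.frame(x = x1, xend = x1, y = y1, yend = height[k]),
                  data.frame(x = x2, xend = x2, y = y2, yend = height[k]),
                  data.frame(x = x1, xend = x2, y = height[k], yend = height[k]))
  }
  leaves <- data.frame(x = unname(xleaf),
                       label = object$labels[as.integer(names(xleaf))])
  nodes <- data.frame(x = nx, y = height,
                      label = sprintf("%d|%d", round(object$nodes$au * 100),
                                      round(object$nodes$bp * 100)),
                      strong = object$nodes$au > au_threshold)
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = segs,
                          ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$label,
                                    colour = .data$strong),
                       vjust = -0.5, size = 3, show.legend = FALSE) +
    ggplot2::geom_text(data = leaves,
                       ggplot2::aes(x = .data$x, y = 0, label = .data$label),
                       angle = 90, hjust = 1.1, size = 3) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#c0392b",
                                            `FALSE` = "grey30")) +
    ggplot2::scale_y_continuous(expand = ggplot2::expansion(mult = c(0.25, 0.15))) +
    ggplot2::labs(x = NULL, y = "1 - Pearson correlation (average linkage)",
                  title = "Sample clustering with AU|BP support (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid.major.x = ggplot2::element_blank())
}

#' Bar chart of relative expression with error bars
#'
#' @param object A [relative_expression()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot relative_expression
#' @export
autoplot.relative_expression <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene, y = .data$value,
                                   fill = .data$sample)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$value - .data$sd,
                                        ymax = .data$value + .data$sd),
                           position = ggplot2::position_dodge(width = 0.8),
                           width = 0.25) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "expression relative to control")
}
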