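#' Plot a unified network
#'
#' Force-directed layout (Fruchterman-Reingold, from igraph) with nodes
#' colored by expansion level and inferred edges drawn dashed.
#'
#' @param object A `unified_network`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.unified_network <- function(object, ...) {
  g <- as_igraph(object)
  xy <- igraph::layout_with_fr(g)
  nodes <- mutate(object$nodes, x = xy[, 1], y = xy[, 2])
  idx <- match(as.character(object$edges$ue_a), as.character(nodes$ue_id))
  jdx <- match(as.character(object$edges$ue_b), as.character(nodes$ue_id))
  edges <- mutate(object$edges,
                  x = nodes$x[idx], y = nodes$y[idx],
                  xend = nodes$x[jdx], yend = nodes$y[jdx])
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linetype = .data$inferred),
      color = "grey55"
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, color = factor(.data$level)),
      size = 3
    ) +
    ggplot2::scale_linetype_manual(values = c(`FALSE` = "solid",
                                              `TRUE` = "dashed"),
                                   name = "inferred") +
    ggplot2::labs(color = "level") +
    ggplot2::theme_void()
}

#' Plot the class-size distribution of a partition
#'
#' @param object A [unify()] result.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.user_entities <- function(object, ...) {
  m <- object$membership[!object$membership$promiscuous, ]
  sizes <- dplyr::count(m, .data$ue_id, name = "size")
  ggplot2::ggplot(sizes, ggplot2::aes(x = .data$size)) +
    ggplot2::geom_bar(fill = "steelblue") +
    ggplot2::labs(x = "records per user entity", y = "user entities") +
    ggplot2::theme_minimal()
}
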