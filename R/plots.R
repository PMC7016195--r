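#' Domain-architecture diagram of annotated sequences
#'
#' Draws each sequence as a horizontal backbone with its detected features
#' (ZCD clusters, C-cys anchor, GDP-site block) as colored blocks and the
#' annotated residues as ticks, the way domain cartoons are usually shown
#' in comparative studies.
#'
#' @param ann a [zcd_annotate()] object.
#' @return A ggplot object.
#' @export
plot_architecture <- function(ann) {
  stopifnot(inherits(ann, "zcd_annotation"))
  seqs <- ann$sequences %>%
    mutate(length = nchar(.data$residues),
           y = as.numeric(factor(.data$id, levels = rev(.data$id))))
  blocks <- list()
  if (nrow(ann$hits) > 0) {
    h <- ann$hits
    blocks$clusters <- bind_rows(
      tibble(seq_id = h$seq_id, start = h$c1_start, end = h$c1_end, feature = "cluster1"),
      tibble(seq_id = h$seq_id, start = h$c2_start, end = h$c2_end, feature = "cluster2"),
      tibble(seq_id = h$seq_id, start = h$c3_start, end = h$c3_end, feature = "cluster3")
    )
  }
  a <- ann$anchors %>% filter(!is.na(.data$start))
  if (nrow(a) > 0) {
    blocks$anchor <- tibble(seq_id = a$seq_id, start = a$start, end = a$end,
                            feature = paste0("anchor (", a$anchor_class, ")"))
  }
  blocks <- bind_rows(blocks)
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seqs,
      ggplot2::aes(x = 1, xend = .data$length, y = .data$y, yend = .data$y),
      linewidth = 0.4, color = "grey40") +
    ggplot2::scale_y_continuous(breaks = seqs$y, labels = seqs$id) +
    ggplot2::labs(x = "residue position (1-based)", y = NULL, fill = "feature") +
    ggplot2::theme_minimal()
  if (nrow(blocks) > 0) {
    blocks <- left_join(blocks, seqs[, c("id", "y")], by = c(seq_id = "id"))
    p <- p + ggplot2::geom_rect(
      data = blocks,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = .data$y - 0.3, ymax = .data$y + 0.3,
                   fill = .data$feature))
  }
  if (nrow(ann$residues) > 0) {
    marks <- left_join(ann$residues, seqs[, c("id", "y")], by = c(seq_id = "id"))
    p <- p + ggplot2::geom_point(
      data = marks,
      ggplot2::aes(x = .data$position, y = .data$y + 0.38),
      shape = "|", size = 2)
  }
  p
}

#' @rdname plot_architecture
#' @param object,... autoplot interface (object is a `zcd_annotation`).
#' @method autoplot zcd_annotation
#' @export
autoplot.zcd_annotation <- function(object, ...) plot_architecture(object)

#' Plot a conserved-synteny graph
#'
#' Focal genes on a circular layout, edges weighted by the number of
#' shared ortholog groups.
#'
#' @param object a [synteny_graph()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot synteny_graph
#' @export
autoplot.synteny_graph <- function(object, ...) {
  nodes <- object$nodes
  n <- nrow(nodes)
  theta <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  layout <- tibble(focal_gene_id = nodes$focal_gene_id,
                   x = cos(theta), y = sin(theta))
  p <- ggplot2::ggplot() +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
  if (nrow(object$edges) > 0) {
    ed <- object$edges %>%
      left_join(layout, by = c(from = "focal_gene_id")) %>%
      rename(x0 = "x", y0 = "y") %>%
      left_join(layout, by = c(to = "focal_gene_id"))
    p <- p + ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x, yend = .data$y,
                   linewidth = .data$weight),
      color = "steelblue", alpha = 0.7) +
      ggplot2::scale_linewidth(range = c(0.3, 2))
  }
  p +
    ggplot2::geom_point(data = layout, ggplot2::aes(.data$x, .data$y), size = 3) +
    ggplot2::geom_text(data = layout,
                       ggplot2::aes(.data$x * 1.15, .data$y * 1.15,
                                    label = .data$focal_gene_id),
                       size = 3)
}
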