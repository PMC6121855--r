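# ggplot2 displays for the main result types.

#' Plot genome-content ordination scores
#'
#' @param object a `ch_ordination`.
#' @param colour optional named vector (genome id -> label, e.g. ecology)
#'   used for point colour.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.ch_ordination <- function(object, colour = NULL, ...) {
  df <- object$scores
  vf <- round(100 * object$variance_fraction[1:2])
  if (!is.null(colour)) df$label <- colour[df$genome_id]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, linetype = 3, colour = "grey70")
  p <- if (is.null(colour)) {
    p + ggplot2::geom_point(size = 2)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$label), size = 2)
  }
  p +
    ggplot2::geom_text(ggplot2::aes(label = .data$genome_id),
                       vjust = -0.8, size = 3) +
    ggplot2::labs(x = paste0("PC1 (", vf[1], "%)"),
                  y = paste0("PC2 (", vf[2], "%)"),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot discovered cluster loci as gene maps
#'
#' One horizontal track per genome; boxes are locus member genes placed at
#' their gene-order coordinate and coloured by homolog group.
#'
#' @param loci locus tibble from [run_discovery()] / [find_colocalized()].
#' @return A ggplot.
#' @export
plot_cluster_loci <- function(loci) {
  stopifnot(nrow(loci) > 0L)
  df <- dplyr::mutate(loci,
                      track = paste(.data$genome_id, .data$locus_id))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$order_index, y = .data$track)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$group_id),
                       width = 0.9, height = 0.6, colour = "grey30") +
    ggplot2::labs(x = "gene order along scaffold", y = NULL,
                  fill = "homolog group") +
    ggplot2::theme_minimal()
}

#' Plot the retention funnel of a transfer screen
#'
#' @param object a `ch_hgt_screen`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.ch_hgt_screen <- function(object, ...) {
  df <- object$report
  df$stage <- factor(df$stage, levels = rev(df$stage))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$stage)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), hjust = -0.2, size = 3) +
    ggplot2::labs(x = "genes retained", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
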