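# ggplot2 views of the main result types.

#' Plot a per-residue mobility profile
#'
#' @param model A `pca_model`.
#' @param pc Component to plot (default 1).
#' @param regions Optional tibble of mobile regions (`start`, `end`) to shade.
#' @return A ggplot object.
#' @export
plot_mobility <- function(model, pc = 1L, regions = NULL) {
  prof <- residue_mobility(model, pc)
  p <- ggplot2::ggplot(prof, ggplot2::aes(x = .data$resno, y = .data$displacement))
  if (!is.null(regions) && nrow(regions) > 0L) {
    p <- p + ggplot2::geom_rect(
      data = regions,
      ggplot2::aes(xmin = .data$start, xmax = .data$end),
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "steelblue",
      inherit.aes = FALSE)
  }
  p + ggplot2::geom_line() +
    ggplot2::labs(x = "Residue", y = "Displacement (unit eigenvector)",
                  title = paste0("PC", pc, " mobility profile"))
}

#' Heatmap of a saturation ΔΔG scan
#'
#' @param scan A [aggregate_scan()] result.
#' @param cap Colour-scale cap in kcal/mol (default 8).
#' @return A ggplot object.
#' @export
plot_ddg_heatmap <- function(scan, cap = 8) {
  df <- dplyr::mutate(scan, ddg = pmin(pmax(.data$mean_ddg, -cap), cap))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$site, y = .data$sub,
                                   fill = .data$ddg)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick",
                                  midpoint = 0, name = "ddG\n(kcal/mol)") +
    ggplot2::labs(x = "Site", y = "Substitution")
}

#' Descriptor dot-matrix of an assessment report
#'
#' One row per mutation, one column per descriptor; damaging descriptors are
#' filled dots, not-evaluated ones are open grey.
#'
#' @param report Output of [score_and_categorize()].
#' @return A ggplot object.
#' @export
plot_descriptors <- function(report) {
  dm <- descriptor_matrix(report)
  dm$mutation <- factor(dm$mutation, levels = rev(sort(unique(dm$mutation))))
  ggplot2::ggplot(dm, ggplot2::aes(x = .data$descriptor, y = .data$mutation,
                                   colour = .data$value, shape = .data$value)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::scale_colour_manual(values = c(damaging = "black",
                                            neutral = "grey70",
                                            not_evaluated = "grey90")) +
    ggplot2::scale_shape_manual(values = c(damaging = 16, neutral = 1,
                                           not_evaluated = 4)) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$layer), scales = "free_x",
                        space = "free_x") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1)) +
    ggplot2::labs(x = NULL, y = NULL, colour = NULL, shape = NULL)
}

#' @rdname plot_descriptors
#' @param object A `psnmut_run`.
#' @param ... Unused.
#' @method autoplot psnmut_run
#' @export
autoplot.psnmut_run <- function(object, ...) plot_descriptors(object$report)
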