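#' Heat map of a COMPACT matrix
#'
#' Tile plot of the comparative pattern counts; by default only rows and
#' columns with nonzero mass are shown, mirroring how COMPACT matrices are
#' reported.
#'
#' @param object An `ra_compact`.
#' @param ... Unused.
#' @param drop_empty Drop all-zero rows/columns, default `TRUE`.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ra_compact <- function(object, ..., drop_empty = TRUE) {
  long <- tidy(object, all_cells = TRUE)
  if (drop_empty) {
    keep_r <- rownames(object$counts)[rowSums(object$counts) > 0]
    keep_c <- colnames(object$counts)[colSums(object$counts) > 0]
    long <- dplyr::filter(long, .data$deab_pattern %in% keep_r,
                          .data$ra_pattern %in% keep_c)
  }
  ggplot2::ggplot(long, ggplot2::aes(
    x = factor(.data$ra_pattern, levels = colnames(object$counts)),
    y = factor(.data$deab_pattern, levels = rev(rownames(object$counts))),
    fill = log10(.data$count + 1))) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(
      data = dplyr::filter(long, .data$count > 0),
      ggplot2::aes(label = .data$count), size = 2.5) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::labs(x = "RA vs Control pattern", y = "DEAB vs Control pattern",
                  fill = "log10(n+1)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Principal-curve trajectory plot
#'
#' Samples in the PC1-PC2 plane, colored by time and shaped by treatment,
#' with the fitted principal curve overlaid and its origin marked.
#'
#' @param object An `ra_trajectory` from [fit_trajectory()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ra_trajectory <- function(object, ...) {
  sc <- object$scores
  curve <- tibble::as_tibble(object$curve$vertices, .name_repair = ~ c("PC1", "PC2", "PC3")[seq_along(.x)])
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::geom_path(data = curve, color = "grey40") +
    ggplot2::geom_point(ggplot2::aes(color = factor(.data$time_h),
                                     shape = .data$treatment), size = 2) +
    ggplot2::annotate("point", x = curve$PC1[1], y = curve$PC2[1],
                      shape = 8, size = 3) +
    ggplot2::labs(title = paste0("Principal curve: ", object$gene_set_label),
                  color = "time (h)", shape = "treatment") +
    ggplot2::theme_minimal()
}

#' Efficiency-efficacy matrix plot
#'
#' Clutches placed by feedback effort (RA-network shift) versus outcome (hox
#' shift), one facet per perturbation arm, with the median cutpoints drawn.
#'
#' @param quadrants Tibble from [efficiency_quadrants()].
#' @return A ggplot object.
#' @export
plot_efficiency_matrix <- function(quadrants) {
  meds <- dplyr::summarise(
    dplyr::group_by(quadrants, .data$treatment),
    mx = median(.data$network_shift), my = median(.data$hox_shift),
    .groups = "drop")
  ggplot2::ggplot(quadrants, ggplot2::aes(x = .data$network_shift,
                                          y = .data$hox_shift)) +
    ggplot2::geom_vline(data = meds, ggplot2::aes(xintercept = .data$mx),
                        linetype = 2, color = "grey60") +
    ggplot2::geom_hline(data = meds, ggplot2::aes(yintercept = .data$my),
                        linetype = 2, color = "grey60") +
    ggplot2::geom_text(ggplot2::aes(label = .data$clutch,
                                    color = .data$quadrant)) +
    ggplot2::facet_wrap(~treatment) +
    ggplot2::labs(x = "RA network shift (feedback effort)",
                  y = "hox shift (outcome)") +
    ggplot2::theme_minimal()
}
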