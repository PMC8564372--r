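#' Tidy a fitted principal curve
#'
#' @param x An `ra_curve` from [fit_principal_curve()].
#' @param ... Unused.
#' @return One row per sample: `sample_id` (when known), `lambda`,
#'   `sq_residual`.
#' @exportS3Method generics::tidy
tidy.ra_curve <- function(x, ...) {
  tibble::tibble(
    sample_id = x$sample_ids %||% as.character(seq_along(x$lambda)),
    lambda = x$lambda,
    sq_residual = x$sq_residual)
}

#' @rdname tidy.ra_curve
#' @return `glance()`: a one-row tibble with `n_vertices`, `n_samples`,
#'   `rss`, `n_iter`, `converged`.
#' @exportS3Method generics::glance
glance.ra_curve <- function(x, ...) {
  tibble::tibble(
    n_vertices = nrow(x$vertices),
    n_samples = length(x$lambda),
    rss = x$rss[length(x$rss)],
    n_iter = x$n_iter,
    converged = x$converged)
}

#' Tidy a trajectory fit
#'
#' @param x An `ra_trajectory` from [fit_trajectory()].
#' @param ... Unused.
#' @return The per-sample lambda tibble with the gene-set label attached.
#' @exportS3Method generics::tidy
tidy.ra_trajectory <- function(x, ...) {
  dplyr::mutate(x$lambda, gene_set = x$gene_set_label)
}

#' @rdname tidy.ra_trajectory
#' @exportS3Method generics::glance
glance.ra_trajectory <- function(x, ...) {
  dplyr::mutate(glance(x$curve), gene_set = x$gene_set_label)
}

#' Tidy a COMPACT matrix
#'
#' @param x An `ra_compact` from [build_compact()].
#' @param ... Unused.
#' @param all_cells Include zero-count cells (default `FALSE`: occupied cells
#'   only, as displayed in COMPACT reports).
#' @return Long tibble: `deab_index`, `ra_index`, `deab_pattern`,
#'   `ra_pattern`, `count`.
#' @exportS3Method generics::tidy
tidy.ra_compact <- function(x, ..., all_cells = FALSE) {
  if (!all_cells) {
    return(dplyr::select(x$cells, -"gene_ids"))
  }
  k <- nrow(x$counts)
  out <- tidyr::expand_grid(deab_index = 0:(k - 1), ra_index = 0:(k - 1))
  out$deab_pattern <- rownames(x$counts)[out$deab_index + 1]
  out$ra_pattern <- colnames(x$counts)[out$ra_index + 1]
  out$count <- as.integer(x$counts[cbind(out$deab_index + 1, out$ra_index + 1)])
  out
}

#' @rdname tidy.ra_compact
#' @exportS3Method generics::glance
glance.ra_compact <- function(x, ...) {
  tibble::tibble(
    t_len = x$t_len,
    n_patterns = nrow(x$counts),
    n_cells = length(x$counts),
    n_genes = x$n_genes,
    occupied_cells = sum(x$counts > 0))
}
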