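#' PCA scores of samples for a gene set
#'
#' Projects the samples of a (typically Z-scored, assay-combined) expression
#' tibble onto the leading principal components of the chosen gene set.
#' Genes are centered but not rescaled (the input is already on a common
#' Z scale); each component's sign is fixed deterministically by flipping it
#' so that its largest-magnitude loading is positive.
#'
#' @param expr Long expression tibble.
#' @param gene_set Character vector of gene ids; at least 3 must be present
#'   in `expr`.
#' @param n_components Number of leading components to keep, default 3.
#' @return Tibble: sample metadata plus `PC1`..`PCn`; attribute `variance`
#'   holds the per-component variance and `loadings` the (sign-fixed)
#'   rotation matrix.
#' @export
pca_scores <- function(expr, gene_set, n_components = 3) {
  check_expression(expr)
  m <- expr_matrix(dplyr::filter(expr, .data$gene_id %in% gene_set))
  if (nrow(m) < 3) {
    abort(sprintf("only %d gene(s) of the set present; need at least 3", nrow(m)))
  }
  pca <- prcomp(t(m), center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pca$rotation))
  rot <- pca$rotation[, seq_len(k), drop = FALSE]
  scores <- pca$x[, seq_len(k), drop = FALSE]
  flip <- vapply(seq_len(k), function(j) {
    v <- rot[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1))
  rot <- sweep(rot, 2, flip, "*")
  scores <- sweep(scores, 2, flip, "*")
  out <- dplyr::inner_join(
    tibble::as_tibble(scores, rownames = "sample_id"),
    expr_metadata(expr), by = "sample_id")
  out <- dplyr::select(out, "sample_id", "clutch", "treatment", "time_h",
                       "assay", dplyr::starts_with("PC"))
  attr(out, "variance") <- pca$sdev[seq_len(k)]^2
  attr(out, "loadings") <- rot
  out
}

#' Fit the robustness trajectory of a gene set
#'
#' Convenience wrapper chaining [pca_scores()] and [fit_principal_curve()]
#' with the study's two-centroid start: the curve origin is the centroid of
#' the 0 h Control samples of all clutches and the second anchor the centroid
#' of all remaining samples, so arc distance `lambda` grows away from the
#' unperturbed washout state.
#'
#' @param expr Combined, Z-scored long expression tibble.
#' @param gene_set Character vector of gene ids.
#' @param gene_set_label Label recorded in the result, e.g. `"hox"`.
#' @param n_components,smoother_df,tol,max_iter Passed to [pca_scores()] and
#'   [fit_principal_curve()].
#' @return An `ra_trajectory` object: `curve` (the `ra_curve`), `scores`,
#'   `lambda` (tibble of sample metadata + `lambda` + `sq_residual`) and
#'   `gene_set_label`.
#' @export
fit_trajectory <- function(expr, gene_set, gene_set_label,
                           n_components = 3, smoother_df = 5,
                           tol = 1e-4, max_iter = 50) {
  scores <- pca_scores(expr, gene_set, n_components)
  pc_cols <- grep("^PC", names(scores), value = TRUE)
  x <- as.matrix(scores[, pc_cols])
  rownames(x) <- scores$sample_id
  is_origin <- scores$treatment == "Control" & scores$time_h == 0
  if (!any(is_origin)) abort("no 0 h Control samples to anchor the curve")
  start_a <- colMeans(x[is_origin, , drop = FALSE])
  start_b <- colMeans(x[!is_origin, , drop = FALSE])
  curve <- fit_principal_curve(x, start_a, start_b, smoother_df = smoother_df,
                               tol = tol, max_iter = max_iter)
  lambda <- dplyr::mutate(
    dplyr::select(scores, "sample_id", "clutch", "treatment", "time_h", "assay"),
    lambda = curve$lambda, sq_residual = curve$sq_residual)
  structure(list(curve = curve, scores = scores, lambda = lambda,
                 gene_set_label = gene_set_label),
            class = "ra_trajectory")
}

#' Net absolute expression shift per clutch and treatment
#'
#' For each clutch and perturbation arm, the per-time normalized deviation is
#' \deqn{d_t = |\lambda_{treat}(t) - \lambda_{Control}(t)| / \max(\lambda)}
#' and the net absolute expression shift is \eqn{s = \sum_t d_t}, summed over
#' all time points. `max(lambda)` is taken over all samples on the gene set's
#' curve (set `max_lambda = "per_clutch"` for a within-clutch denominator).
#' A lower `s` means the clutch held its transcriptional state closer to its
#' own control — i.e., was more robust to that perturbation. If several
#' samples share a (clutch, treatment, time) cell their `lambda` values are
#' averaged first.
#'
#' @param trajectory An `ra_trajectory` from [fit_trajectory()], or its
#'   `lambda` tibble.
#' @param max_lambda `"global"` (default) or `"per_clutch"`.
#' @param gene_set_label Override for the `gene_set` column when a bare
#'   lambda tibble is supplied.
#' @return Tibble: `clutch`, `treatment`, `gene_set`, `time_h`, `d`
#'   (per-time deviation) and `s` (the per-clutch net shift, repeated across
#'   the time rows). Use [shift_summary()] for the one-row-per-clutch form.
#' @export
expression_shift <- function(trajectory, max_lambda = c("global", "per_clutch"),
                             gene_set_label = NULL) {
  max_lambda <- match.arg(max_lambda)
  if (inherits(trajectory, "ra_trajectory")) {
    lam <- trajectory$lambda
    gene_set_label <- gene_set_label %||% trajectory$gene_set_label
  } else {
    lam <- trajectory
    gene_set_label <- gene_set_label %||% "gene_set"
  }
  cell <- dplyr::summarise(
    dplyr::group_by(lam, .data$clutch, .data$treatment, .data$time_h),
    lambda = mean(.data$lambda), .groups = "drop")
  ctrl <- dplyr::select(dplyr::filter(cell, .data$treatment == "Control"),
                        "clutch", "time_h", ctrl_lambda = "lambda")
  trt <- dplyr::filter(cell, .data$treatment != "Control")
  paired <- dplyr::full_join(trt, ctrl, by = c("clutch", "time_h"))
  if (anyNA(paired$lambda) || anyNA(paired$ctrl_lambda)) {
    abort("missing sample for some (clutch, treatment, time) cell")
  }
  denom <- if (max_lambda == "global") max(lam$lambda) else NULL
  out <- dplyr::group_by(paired, .data$clutch)
  out <- dplyr::mutate(out, denom = denom %||% max(.data$lambda, .data$ctrl_lambda))
  out <- dplyr::ungroup(out)
  if (any(out$denom <= 0)) abort("maximum lambda is zero; degenerate curve")
  out <- dplyr::mutate(out,
                       d = abs(.data$lambda - .data$ctrl_lambda) / .data$denom,
                       gene_set = gene_set_label)
  out <- dplyr::mutate(dplyr::group_by(out, .data$clutch, .data$treatment),
                       s = sum(.data$d))
  dplyr::arrange(
    dplyr::select(dplyr::ungroup(out), "clutch", "treatment", "gene_set",
                  "time_h", "d", "s"),
    .data$treatment, .data$clutch, .data$time_h)
}

#' Collapse a shift table to one row per clutch x treatment
#'
#' @param shift Tibble from [expression_shift()] (several gene sets may be
#'   row-bound).
#' @return Tibble: `clutch`, `treatment`, `gene_set`, `s`.
#' @export
shift_summary <- function(shift) {
  dplyr::distinct(shift, .data$clutch, .data$treatment, .data$gene_set, .data$s)
}

#' Rank clutches by robustness to a perturbation
#'
#' Sorts clutches by ascending net absolute expression shift for the chosen
#' gene set and treatment — most robust (smallest shift) first — breaking
#' ties lexicographically by clutch id.
#'
#' @param shift Tibble from [expression_shift()].
#' @param gene_set_label Gene set to rank on, e.g. `"hox"`.
#' @param treatment Perturbation arm, e.g. `"RA"`.
#' @return Tibble in rank order: `clutch`, `treatment`, `gene_set`, `s`,
#'   `rank`.
#' @export
rank_clutches <- function(shift, gene_set_label, treatment) {
  x <- shift_summary(shift)
  x <- dplyr::filter(x, .data$gene_set == gene_set_label,
                     .data$treatment == !!treatment)
  if (nrow(x) == 0) abort("no shifts for that gene set / treatment")
  x <- x[order(x$s, x$clutch), ]
  x$rank <- seq_len(nrow(x))
  x
}

#' Efficiency-efficacy quadrants of the clutch robustness responses
#'
#' Places every clutch, per perturbation arm, on a 2-D map of feedback effort
#' (x: RA-network gene-set shift) versus phenotypic outcome (y: hox gene-set
#' shift) and labels the four quadrants cut at the across-clutch median of
#' each axis (boundary values count as low): low effort / low outcome shift =
#' `efficient-effective`; high effort / low outcome = `effective-inefficient`
#' (robustness achieved at high cost); low effort / high outcome =
#' `ineffective`; high effort / high outcome = `inefficient-ineffective`.
#' When an axis is constant across clutches every clutch falls in the
#' boundary-inclusive low half and a warning is raised.
#'
#' @param shift Row-bound [expression_shift()] tables holding both the
#'   `hox` and `ra_network` gene sets.
#' @param hox_label,network_label Gene-set labels of the outcome and effort
#'   axes.
#' @return Tibble: `clutch`, `treatment`, `network_shift`, `hox_shift`,
#'   `quadrant`.
#' @export
efficiency_quadrants <- function(shift, hox_label = "hox",
                                 network_label = "ra_network") {
  x <- shift_summary(shift)
  hox <- dplyr::filter(x, .data$gene_set == hox_label)
  net <- dplyr::filter(x, .data$gene_set == network_label)
  if (nrow(hox) == 0 || nrow(net) == 0) {
    abort("need shifts for both the hox and the RA-network gene sets")
  }
  both <- dplyr::inner_join(
    dplyr::select(hox, "clutch", "treatment", hox_shift = "s"),
    dplyr::select(net, "clutch", "treatment", network_shift = "s"),
    by = c("clutch", "treatment"))
  if (nrow(both) < nrow(hox)) abort("clutch x treatment mismatch between gene sets")
  both <- dplyr::mutate(
    dplyr::group_by(both, .data$treatment),
    low_hox = .data$hox_shift <= median(.data$hox_shift),
    low_net = .data$network_shift <= median(.data$network_shift))
  degenerate <- dplyr::summarise(
    both,
    deg = sd(.data$hox_shift) == 0 || sd(.data$network_shift) == 0)
  if (any(degenerate$deg)) {
    warn("degenerate shift distribution: all clutches identical on an axis")
  }
  both <- dplyr::ungroup(both)
  both$quadrant <- dplyr::case_when(
    both$low_net & both$low_hox ~ "efficient-effective",
    !both$low_net & both$low_hox ~ "effective-inefficient",
    both$low_net & !both$low_hox ~ "ineffective",
    TRUE ~ "inefficient-ineffective")
  dplyr::select(both, "clutch", "treatment", "network_shift", "hox_shift",
                "quadrant")
}
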