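#' Remove genes below a minimum expression level in every sample
#'
#' A gene is dropped only when its value is below `min_count` in all samples;
#' a single sample at or above the threshold keeps the gene. Intended for
#' count-scale data before log transformation; inputs tagged as log2 or
#' Z-scaled are rejected.
#'
#' @param expr Long expression tibble on the count scale.
#' @param min_count Threshold (>= 0), default 5.
#' @return The filtered tibble, gene order preserved.
#' @export
filter_min_expression <- function(expr, min_count = 5) {
  check_expression(expr)
  if (min_count < 0) abort("min_count must be non-negative")
  if (expr_scale(expr) %in% c("log2", "zscore")) {
    abort(paste0("filter_min_expression expects count-scale data, got '",
                 expr_scale(expr), "'"))
  }
  keep <- dplyr::summarise(dplyr::group_by(expr, .data$gene_id),
                           keep = any(.data$value >= min_count),
                           .groups = "drop")
  out <- dplyr::semi_join(expr, dplyr::filter(keep, keep), by = "gene_id")
  set_expr_scale(out, expr_scale(expr))
}

#' Log2-transform counts with a pseudocount
#'
#' @param expr Long expression tibble of non-negative counts.
#' @param pseudocount Positive offset added before taking log2, default 1.
#' @return The transformed tibble, scale recorded as `log2`.
#' @export
log2_transform <- function(expr, pseudocount = 1) {
  check_expression(expr)
  if (pseudocount <= 0) abort("pseudocount must be positive")
  if (any(expr$value < 0)) abort("negative values cannot be log2-transformed")
  out <- dplyr::mutate(expr, value = log2(.data$value + pseudocount))
  set_expr_scale(out, "log2")
}

#' Quantile-normalize samples of an expression tibble
#'
#' Forces every sample's value distribution to the common reference formed by
#' averaging order statistics across samples, preserving within-sample ranks;
#' tied values receive the mean of the tied order-statistic means. Delegates
#' to [limma::normalizeQuantiles()].
#'
#' @param expr Long expression tibble with at least two samples.
#' @return The normalized tibble, same scale tag as the input.
#' @export
quantile_normalize <- function(expr) {
  check_expression(expr)
  m <- expr_matrix(expr)
  if (ncol(m) < 2) abort("quantile normalization needs at least 2 samples")
  qn <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(qn) <- dimnames(m)
  expr_from_matrix(qn, expr_metadata(expr), scale = expr_scale(expr))
}

#' Z-score each gene across the samples of its assay
#'
#' Centers and scales every gene row to mean 0 and sample (n - 1) standard
#' deviation 1. Genes with zero variance carry no dynamic information and are
#' dropped with a warning rather than zero-filled, which would fabricate
#' flat patterns. Idempotent.
#'
#' @param expr Long expression tibble (one assay).
#' @return The Z-scored tibble, scale recorded as `zscore`.
#' @export
zscore_genes <- function(expr) {
  check_expression(expr)
  m <- expr_matrix(expr)
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  constant <- s < .Machine$double.eps^0.5 * pmax(1, abs(mu))
  if (any(constant)) {
    warn(sprintf("dropping %d constant gene(s): %s", sum(constant),
                 paste(head(rownames(m)[constant], 5), collapse = ", ")))
    m <- m[!constant, , drop = FALSE]
    mu <- mu[!constant]
    s <- s[!constant]
  }
  z <- (m - mu) / s
  expr_from_matrix(z, expr_metadata(expr), scale = "zscore")
}

#' Relative expression from a Ct table by the delta-delta-Ct method
#'
#' Per gene and sample, the Ct is the median over the three pre-amplification
#' groups of the median over technical replicates (the median-of-groups rule
#' absorbs L/S homeolog-specific primer-pool differences). Then
#' `dCt = Ct_gene - Ct_housekeeping` within each sample, `ddCt` subtracts the
#' `dCt` of the clutch's own reference sample, and the reported log2 relative
#' expression is `-ddCt` (one cycle fewer = twofold more transcript).
#'
#' @param ct Long Ct tibble as produced by [simulate_ct_table()]: `gene_id`,
#'   `sample_id`, `clutch`, `treatment`, `time_h`, `preamp_group`,
#'   `tech_replicate`, `ct`; attribute `housekeeping` names the housekeeping
#'   gene (default `gapdh.S`).
#' @param reference_treatment,reference_time The reference sample of each
#'   clutch, default Control at 0 h.
#' @return Long expression tibble of log2 relative expression (`assay` =
#'   `htqpcr`), scale recorded as `log2`.
#' @export
delta_delta_ct <- function(ct, reference_treatment = "Control",
                           reference_time = 0) {
  housekeeping <- attr(ct, "housekeeping") %||% "gapdh.S"
  if (!housekeeping %in% ct$gene_id) {
    abort(paste0("housekeeping gene ", housekeeping, " missing from Ct table"))
  }
  per_sample <- dplyr::summarise(
    dplyr::group_by(ct, .data$gene_id, .data$sample_id, .data$clutch,
                    .data$treatment, .data$time_h, .data$preamp_group),
    ct = median(.data$ct), .groups = "drop_last")
  per_sample <- dplyr::summarise(per_sample, ct = median(.data$ct),
                                 .groups = "drop")

  hk <- dplyr::select(
    dplyr::filter(per_sample, .data$gene_id == housekeeping),
    "sample_id", hk_ct = "ct")
  missing_hk <- setdiff(unique(per_sample$sample_id), hk$sample_id)
  if (length(missing_hk) > 0) {
    abort(paste0("housekeeping measurement missing for sample(s): ",
                 paste(head(missing_hk, 5), collapse = ", ")))
  }
  dct <- dplyr::mutate(
    dplyr::inner_join(per_sample, hk, by = "sample_id"),
    dct = .data$ct - .data$hk_ct)

  ref <- dplyr::filter(dct, .data$treatment == reference_treatment,
                       .data$time_h == reference_time)
  if (nrow(ref) == 0) {
    abort(sprintf("reference group (%s, %g h) not present",
                  reference_treatment, reference_time))
  }
  ref <- dplyr::select(ref, "gene_id", "clutch", ref_dct = "dct")
  out <- dplyr::mutate(
    dplyr::inner_join(dct, ref, by = c("gene_id", "clutch")),
    value = -(.data$dct - .data$ref_dct),
    assay = "htqpcr")
  out <- dplyr::filter(out, .data$gene_id != housekeeping)
  set_expr_scale(dplyr::select(out, dplyr::all_of(EXPR_COLS)), "log2")
}

#' Combine two independently Z-scored assays into one matrix
#'
#' Column-concatenates two expression tibbles restricted to their shared gene
#' panel. Both inputs must already be Z-scored (each within its own assay, so
#' assay-level batch structure is neutralized before pooling) and must not
#' share sample ids.
#'
#' @param z_a,z_b Z-scored long expression tibbles.
#' @return The combined tibble, scale `zscore`.
#' @export
combine_assays <- function(z_a, z_b) {
  check_expression(z_a)
  check_expression(z_b)
  if (expr_scale(z_a) != "zscore" || expr_scale(z_b) != "zscore") {
    abort("both inputs must be Z-scored (see zscore_genes())")
  }
  shared <- intersect(unique(z_a$gene_id), unique(z_b$gene_id))
  if (length(shared) == 0) abort("the two assays share no genes")
  if (length(intersect(unique(z_a$sample_id), unique(z_b$sample_id))) > 0) {
    abort("sample ids overlap between the two assays")
  }
  out <- dplyr::bind_rows(
    dplyr::filter(z_a, .data$gene_id %in% shared),
    dplyr::filter(z_b, .data$gene_id %in% shared))
  set_expr_scale(out, "zscore")
}
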