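#' Run the full RA robustness analysis on a simulated study
#'
#' Chains every stage on one seed-determined simulated dataset: simulate the
#' multi-clutch pulse-chase study; quantile-normalize the RNA-seq-like half
#' and gate genes with the per-gene two-way ANOVA + BH filter; average
#' clutches and discretize the recovery kinetics (t0-referenced, twofold
#' threshold, 27-pattern space) and the control-referenced responses
#' (1.3-fold threshold, 81-pattern space); cross the RA and DEAB pattern sets
#' into the COMPACT matrix, coarse-grain it by onset and classify genes into
#' response categories; then Z-score both assay halves, convert the qPCR Ct
#' table by delta-delta-Ct, combine to the full clutch x treatment x time
#' sample grid and run the principal-curve trajectory analysis for the hox
#' and RA-network gene sets, yielding net shifts, robustness ranks and
#' efficiency-efficacy quadrants.
#'
#' @param config A [sim_config()]; its seed fixes every random draw, so two
#'   runs with the same config are identical.
#' @param outdir Optional directory; when given, every intermediate table is
#'   written there as TSV/CSV together with a machine-readable
#'   `summary.json`.
#' @param q_threshold,fold_t0,fold_control Significance and discretization
#'   thresholds (BH q cutoff; linear fold thresholds of the t0-referenced and
#'   control-referenced analyses).
#' @param smoother_df,tol,max_iter,max_lambda Trajectory settings, see
#'   [fit_principal_curve()] and [expression_shift()].
#' @return An `ra_run` list: `sim`, `significance`, `patterns_t0`,
#'   `counts_t0`, `overlap_t0`, `patterns_control`, `compact`, `coarse`,
#'   `categories`, `trajectories`, `shift`, `ranks`, `quadrants`, `summary`.
#' @export
run_pipeline <- function(config = sim_config(), outdir = NULL,
                         q_threshold = 0.05, fold_t0 = 2, fold_control = 1.3,
                         smoother_df = 5, tol = 1e-4, max_iter = 50,
                         max_lambda = "global") {
  sim <- simulate_dataset(config)
  rnaseq <- dplyr::filter(sim$expression, .data$assay == "rnaseq")
  rnaseq <- set_expr_scale(rnaseq, "log2")

  rnaseq_qn <- quantile_normalize(rnaseq)
  significance <- significance_filter(rnaseq_qn, q_threshold)
  sig_genes <- significance$gene_id[significance$significant]

  averaged <- clutch_mean(rnaseq_qn)
  avg_sig <- dplyr::filter(averaged, .data$gene_id %in% sig_genes)

  patterns_t0 <- discretize_patterns(differential_vs_t0(avg_sig), fold_t0)
  counts_t0 <- count_patterns(patterns_t0)
  overlap_t0 <- if (length(sig_genes) > 0 &&
                    dplyr::n_distinct(patterns_t0$comparison) >= 2) {
    pattern_overlap(patterns_t0)
  } else NULL

  patterns_control <- discretize_patterns(differential_vs_control(avg_sig),
                                          fold_control)
  p_ra <- dplyr::filter(patterns_control, .data$comparison == "RA")
  p_deab <- dplyr::filter(patterns_control, .data$comparison == "DEAB")
  compact <- build_compact(p_deab, p_ra)
  coarse <- coarse_grain(compact, times = config$times_h)
  categories <- classify_response(p_ra, p_deab)

  z_rna <- zscore_genes(rnaseq)
  ddct <- delta_delta_ct(sim$ct)
  z_qpcr <- zscore_genes(ddct)
  combined <- combine_assays(z_rna, z_qpcr)

  sets <- ra_gene_sets()
  trajectories <- purrr::imap(sets, function(ids, label) {
    fit_trajectory(combined, ids, label, smoother_df = smoother_df,
                   tol = tol, max_iter = max_iter)
  })
  shift <- dplyr::bind_rows(purrr::map(trajectories, expression_shift,
                                       max_lambda = max_lambda))
  ranks <- dplyr::bind_rows(purrr::map(names(sets), function(label) {
    dplyr::bind_rows(
      rank_clutches(shift, label, "RA"),
      rank_clutches(shift, label, "DEAB"))
  }))
  quadrants <- efficiency_quadrants(shift)

  summary <- list(
    seed = config$seed,
    n_genes = config$n_genes,
    n_samples_total = dplyr::n_distinct(sim$expression$sample_id),
    n_samples_combined = dplyr::n_distinct(combined$sample_id),
    n_significant = length(sig_genes),
    pattern_space_t0 = 3^length(setdiff(config$times_h, 0)),
    occupied_patterns_t0 = length(unique(
      counts_t0$pattern_index[counts_t0$count > 0])),
    compact_dim = dim(compact$counts),
    compact_total = sum(compact$counts),
    occupied_compact_cells = sum(compact$counts > 0),
    coarse_dim = dim(coarse),
    coarse_total = sum(coarse),
    category_counts = as.list(table(categories$category)),
    shift = shift_summary(shift),
    quadrants = quadrants
  )

  run <- structure(
    list(sim = sim, significance = significance, patterns_t0 = patterns_t0,
         counts_t0 = counts_t0, overlap_t0 = overlap_t0,
         patterns_control = patterns_control, compact = compact,
         coarse = coarse, categories = categories,
         trajectories = trajectories, shift = shift, ranks = ranks,
         quadrants = quadrants, summary = summary),
    class = "ra_run")

  if (!is.null(outdir)) write_run(run, outdir)
  run
}

write_run <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)
  write_expression_tsv(run$sim$expression, p("expression.tsv"),
                       p("sample_metadata.tsv"))
  utils::write.table(run$significance, p("significance.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_pattern_counts_tsv(run$counts_t0, p("pattern_counts_t0.tsv"))
  write_compact_csv(run$compact, p("compact.csv"), p("compact_long.tsv"))
  utils::write.csv(run$coarse, p("compact_coarse.csv"), quote = FALSE)
  utils::write.table(run$categories, p("response_categories.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_shift_tsv(run$shift, p("shift_table.tsv"), ranks = run$ranks,
                  quadrants = run$quadrants)
  jsonlite::write_json(run$summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' @export
print.ra_run <- function(x, ...) {
  s <- x$summary
  cat("RA robustness pipeline run\n")
  cat(sprintf("  seed %d | %d genes | %d samples (%d combined for trajectory)\n",
              s$seed, s$n_genes, s$n_samples_total, s$n_samples_combined))
  cat(sprintf("  significant genes: %d | COMPACT %d x %d (%d occupied cells)\n",
              s$n_significant, s$compact_dim[1], s$compact_dim[2],
              s$occupied_compact_cells))
  invisible(x)
}
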