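fmt_num <- function(x) sprintf("%.17g", x)

#' Read and write expression matrices as TSV with a metadata sidecar
#'
#' The matrix file has genes in rows (`gene_id` first column) and samples in
#' columns; the sidecar has one row per sample (`sample_id`, `clutch`,
#' `treatment`, `time_h`, `assay`). Values are written with 17 significant
#' digits so a write/read round trip reproduces doubles exactly.
#'
#' @param expr Long expression tibble.
#' @param path,metadata_path Paths of the matrix and sidecar TSVs.
#' @return `read_expression_tsv()` returns the long expression tibble;
#'   `write_expression_tsv()` returns `path` invisibly.
#' @export
write_expression_tsv <- function(expr, path, metadata_path) {
  check_expression(expr)
  m <- expr_matrix(expr)
  df <- data.frame(gene_id = rownames(m),
                   apply(m, 2, fmt_num),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- expr_metadata(expr)
  utils::write.table(meta, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @param scale Scale tag to record on the result (`"counts"`, `"log2"`,
#'   `"zscore"`, ...).
#' @export
read_expression_tsv <- function(path, metadata_path, scale = "unknown") {
  raw <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  if (nrow(raw) == 0) abort(paste0("empty expression file: ", path))
  if (anyDuplicated(raw$gene_id)) abort("duplicated gene ids in matrix file")
  meta <- utils::read.delim(metadata_path, check.names = FALSE)
  if (anyDuplicated(meta$sample_id)) abort("duplicated sample ids in metadata")
  sample_cols <- setdiff(names(raw), "gene_id")
  missing <- setdiff(sample_cols, meta$sample_id)
  if (length(missing) > 0) {
    abort(paste0("metadata missing for sample(s): ",
                 paste(missing, collapse = ", ")))
  }
  vals <- suppressWarnings(
    vapply(raw[sample_cols], as.numeric, numeric(nrow(raw))))
  vals <- matrix(vals, nrow = nrow(raw),
                 dimnames = list(raw$gene_id, sample_cols))
  if (anyNA(vals)) abort("non-numeric cells in expression matrix")
  expr_from_matrix(vals, tibble::as_tibble(meta), scale = scale)
}

#' Write a pattern-count table as TSV
#'
#' One row per comparison x pattern: `comparison`, `pattern_index`,
#' `pattern`, `count`, `gene_ids` (comma-joined).
#'
#' @param counts Tibble from [count_patterns()].
#' @param path Output path.
#' @export
write_pattern_counts_tsv <- function(counts, path) {
  out <- dplyr::mutate(counts,
                       gene_ids = purrr::map_chr(.data$gene_ids, paste,
                                                 collapse = ","))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a COMPACT matrix as dense CSV and long TSV
#'
#' @param compact An `ra_compact`.
#' @param csv_path Dense K x K counts, DEAB patterns in rows, RA patterns in
#'   columns.
#' @param long_path Optional long-format TSV of the occupied cells with gene
#'   lists.
#' @export
write_compact_csv <- function(compact, csv_path, long_path = NULL) {
  utils::write.csv(compact$counts, csv_path, quote = FALSE)
  if (!is.null(long_path)) {
    long <- dplyr::mutate(compact$cells,
                          gene_ids = purrr::map_chr(.data$gene_ids, paste,
                                                    collapse = ","))
    utils::write.table(long, long_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(csv_path)
}

#' Write a shift table as wide TSV
#'
#' Columns: `clutch`, `treatment`, `gene_set`, one `d_<time>h` column per
#' time point, `s`, and — when available via `ranks` / `quadrants` —
#' `rank` and `quadrant`.
#'
#' @param shift Tibble from [expression_shift()].
#' @param path Output path.
#' @param ranks Optional row-bound [rank_clutches()] results.
#' @param quadrants Optional [efficiency_quadrants()] result.
#' @export
write_shift_tsv <- function(shift, path, ranks = NULL, quadrants = NULL) {
  wide <- tidyr::pivot_wider(shift, names_from = "time_h", values_from = "d",
                             names_prefix = "d_")
  names(wide) <- sub("^(d_[0-9.]+)$", "\\1h", names(wide))
  wide <- dplyr::relocate(wide, "s", .after = dplyr::last_col())
  if (!is.null(ranks)) {
    wide <- dplyr::left_join(
      wide, dplyr::select(ranks, "clutch", "treatment", "gene_set", "rank"),
      by = c("clutch", "treatment", "gene_set"))
  }
  if (!is.null(quadrants)) {
    wide <- dplyr::left_join(
      wide, dplyr::select(quadrants, "clutch", "treatment", "quadrant"),
      by = c("clutch", "treatment"))
  }
  utils::write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a one-id-per-line gene list
#'
#' @param path Text file with one gene id per line.
#' @return Character vector of ids.
#' @export
read_gene_list <- function(path) {
  ids <- readLines(path, warn = FALSE)
  ids <- trimws(ids[nzchar(trimws(ids))])
  if (length(ids) == 0) abort(paste0("empty gene list file: ", path))
  ids
}

#' Read a run configuration from YAML or JSON
#'
#' Recognized top-level keys: any [sim_config()] argument under `simulation`,
#' and the analysis thresholds `min_count`, `q_threshold`, `fold_t0`,
#' `fold_control`, plus trajectory settings `smoother_df`, `tol`, `max_iter`,
#' `max_lambda`. Missing keys fall back to package defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return List with elements `config` (a `sim_config`) and `thresholds`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  sim_args <- raw$simulation %||% list()
  if (!is.null(sim_args$times_h)) sim_args$times_h <- as.numeric(sim_args$times_h)
  if (!is.null(sim_args$class_proportions)) {
    sim_args$class_proportions <- unlist(sim_args$class_proportions)
  }
  config <- do.call(sim_config, sim_args)
  defaults <- list(min_count = 5, q_threshold = 0.05, fold_t0 = 2,
                   fold_control = 1.3, smoother_df = 5, tol = 1e-4,
                   max_iter = 50, max_lambda = "global")
  thresholds <- utils::modifyList(defaults,
                                  raw[intersect(names(raw), names(defaults))])
  list(config = config, thresholds = thresholds)
}
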