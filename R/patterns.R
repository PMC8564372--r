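#' Average expression across clutches within each treatment x time cell
#'
#' @param expr Long expression tibble.
#' @return Tibble: `gene_id`, `treatment`, `time_h`, `value` (the arithmetic
#'   mean across clutches).
#' @export
clutch_mean <- function(expr) {
  check_expression(expr)
  out <- dplyr::summarise(
    dplyr::group_by(expr, .data$gene_id, .data$treatment, .data$time_h),
    value = mean(.data$value), n_clutches = dplyr::n(), .groups = "drop")
  if (any(out$n_clutches == 0)) abort("empty treatment x time cell")
  dplyr::select(out, -"n_clutches")
}

#' Differential expression of each treatment arm relative to its 0 h sample
#'
#' Subtracts the washout (t = 0) level of the same treatment arm, yielding a
#' recovery-kinetics profile over the chase time points for every arm
#' (including Control, whose profile captures the developmental drift).
#'
#' @param averaged Clutch-averaged tibble from [clutch_mean()].
#' @return Tibble: `gene_id`, `comparison` (the treatment arm), `time_h`
#'   (chase times only), `diff`.
#' @export
differential_vs_t0 <- function(averaged) {
  t0 <- dplyr::filter(averaged, .data$time_h == 0)
  if (nrow(t0) == 0) abort("no t = 0 column present")
  t0 <- dplyr::select(t0, "gene_id", "treatment", ref = "value")
  out <- dplyr::inner_join(dplyr::filter(averaged, .data$time_h != 0), t0,
                           by = c("gene_id", "treatment"))
  out <- dplyr::mutate(out, diff = .data$value - .data$ref,
                       comparison = .data$treatment)
  dplyr::arrange(
    dplyr::select(out, "gene_id", "comparison", "time_h", "diff"),
    .data$comparison, .data$gene_id, .data$time_h)
}

#' Differential expression of a treatment relative to Control at each time
#'
#' Subtracts the Control level at the matching time point, removing the
#' shared developmental trend and leaving the perturbation response proper,
#' at all time points including the washout.
#'
#' @param averaged Clutch-averaged tibble from [clutch_mean()].
#' @param treatment Treatment arm(s) to contrast against Control; default all
#'   non-Control arms present.
#' @return Tibble: `gene_id`, `comparison` (the treatment), `time_h`, `diff`.
#' @export
differential_vs_control <- function(averaged, treatment = NULL) {
  ctrl <- dplyr::filter(averaged, .data$treatment == "Control")
  if (nrow(ctrl) == 0) abort("no Control samples present")
  trts <- treatment %||% setdiff(unique(averaged$treatment), "Control")
  ctrl <- dplyr::select(ctrl, "gene_id", "time_h", ref = "value")
  out <- dplyr::inner_join(
    dplyr::filter(averaged, .data$treatment %in% trts), ctrl,
    by = c("gene_id", "time_h"))
  out <- dplyr::mutate(out, diff = .data$value - .data$ref,
                       comparison = .data$treatment)
  dplyr::arrange(
    dplyr::select(out, "gene_id", "comparison", "time_h", "diff"),
    .data$comparison, .data$gene_id, .data$time_h)
}

# ternary encoding ------------------------------------------------------------

#' Encode and decode ternary dynamic patterns
#'
#' A dynamic pattern is an ordered vector over T time points with entries in
#' \{-1, 0, +1\} (down / no change / up). Patterns map bijectively onto the
#' integers `[0, 3^T)` by reading the entries as base-3 digits
#' (`-1 -> 0, 0 -> 1, +1 -> 2`), earliest time point most significant:
#' `index = sum_t (v_t + 1) * 3^(T - 1 - t)`.
#'
#' @param values Integer vector with entries in \{-1, 0, +1\}.
#' @return `pattern_index()`: a single integer. `pattern_decode()`: an integer
#'   vector of length `T`. `pattern_string()`: a compact label such as
#'   `"+00-"`.
#' @examples
#' pattern_index(c(1, 0, -1))        # 23
#' pattern_decode(23, 3)             # c(1, 0, -1)
#' pattern_string(c(1, 0, 0, -1))    # "+00-"
#' @export
pattern_index <- function(values) {
  if (!all(values %in% c(-1, 0, 1))) abort("pattern entries must be -1, 0 or +1")
  t_len <- length(values)
  sum((values + 1) * 3^(t_len - seq_len(t_len)))
}

#' @rdname pattern_index
#' @param index Integer in `[0, 3^t_len)`.
#' @param t_len Number of time points T.
#' @export
pattern_decode <- function(index, t_len) {
  if (index < 0 || index >= 3^t_len) abort("index out of range")
  digits <- integer(t_len)
  for (i in seq_len(t_len)) {
    p <- 3^(t_len - i)
    digits[i] <- index %/% p
    index <- index %% p
  }
  digits - 1L
}

#' @rdname pattern_index
#' @export
pattern_string <- function(values) {
  paste(c("-", "0", "+")[values + 2], collapse = "")
}

#' Discretize differential profiles into ternary dynamic patterns
#'
#' Converts each gene's differential time profile into a pattern of
#' \{-1, 0, +1\} calls: with `tau = log2(fold_threshold_linear)`, a time point
#' is called +1 when the log2 difference is `>= tau`, -1 when `<= -tau`, and
#' 0 otherwise (the boundary counts as a call). For T = 4 time points this
#' admits 81 distinct patterns; for T = 3, 27.
#'
#' @param diffs Tibble from [differential_vs_t0()] or
#'   [differential_vs_control()]: `gene_id`, `comparison`, `time_h`, `diff`
#'   on the log2 scale.
#' @param fold_threshold_linear Linear fold-change threshold (> 1); the
#'   recovery-kinetics analysis uses 2, the control-referenced COMPACT
#'   analysis 1.3.
#' @return Tibble: `gene_id`, `comparison`, `pattern` (string),
#'   `pattern_index`, `t_len`.
#' @export
discretize_patterns <- function(diffs, fold_threshold_linear) {
  if (fold_threshold_linear <= 1) abort("fold threshold must exceed 1")
  tau <- log2(fold_threshold_linear)
  calls <- dplyr::mutate(
    dplyr::arrange(diffs, .data$comparison, .data$gene_id, .data$time_h),
    call = (.data$diff >= tau) - (.data$diff <= -tau))
  out <- dplyr::summarise(
    dplyr::group_by(calls, .data$comparison, .data$gene_id),
    pattern = pattern_string(.data$call),
    pattern_index = pattern_index(.data$call),
    t_len = dplyr::n(), .groups = "drop")
  if (dplyr::n_distinct(out$t_len) > 1) {
    abort("genes have differing numbers of time points")
  }
  dplyr::select(out, "gene_id", "comparison", "pattern", "pattern_index", "t_len")
}

#' Tabulate dynamic patterns over the complete pattern space
#'
#' @param patterns Tibble from [discretize_patterns()] (one comparison, or
#'   several — counting is per comparison).
#' @return Tibble with one row per comparison x pattern index (all `3^T`
#'   indices, zero counts included): `comparison`, `pattern_index`, `pattern`,
#'   `count`, `gene_ids` (list column).
#' @export
count_patterns <- function(patterns) {
  t_len <- unique(patterns$t_len)
  if (length(t_len) != 1) abort("patterns mix different numbers of time points")
  all_idx <- 0:(3^t_len - 1)
  grid <- tidyr::expand_grid(comparison = unique(patterns$comparison),
                             pattern_index = all_idx)
  grid$pattern <- vapply(grid$pattern_index,
                         function(i) pattern_string(pattern_decode(i, t_len)),
                         character(1))
  counts <- dplyr::summarise(
    dplyr::group_by(patterns, .data$comparison, .data$pattern_index),
    count = dplyr::n(), gene_ids = list(sort(.data$gene_id)),
    .groups = "drop")
  out <- dplyr::left_join(grid, counts, by = c("comparison", "pattern_index"))
  out$count[is.na(out$count)] <- 0L
  out$gene_ids <- purrr::map(out$gene_ids, function(g) g %||% character(0))
  attr(out, "t_len") <- t_len
  out
}

#' Per-pattern overlap of gene memberships between comparison groups
#'
#' For every pattern, partitions the genes showing that pattern in at least
#' one group into exclusive and shared Venn regions, quantifying how much of
#' the response is treatment-specific.
#'
#' @param patterns Tibble from [discretize_patterns()] holding two or more
#'   comparisons.
#' @param drop_zero Drop the all-zero (no-change) pattern before computing
#'   overlaps, default TRUE, so fractions describe responsive genes.
#' @return List with `by_pattern` (tibble: `pattern_index`, `pattern`,
#'   `region` — comma-joined group names — `count`, `fraction` within the
#'   pattern) and `summary` (tibble per region over all patterns, with
#'   `fraction` of all counted genes; exclusive regions are single group
#'   names).
#' @export
pattern_overlap <- function(patterns, drop_zero = TRUE) {
  t_len <- unique(patterns$t_len)
  if (length(t_len) != 1) abort("patterns mix different numbers of time points")
  groups <- sort(unique(patterns$comparison))
  if (length(groups) < 2) abort("need at least two comparison groups")
  x <- patterns
  if (drop_zero) {
    zero_idx <- pattern_index(rep(0L, t_len))
    x <- dplyr::filter(x, .data$pattern_index != zero_idx)
  }
  regions <- dplyr::summarise(
    dplyr::group_by(x, .data$pattern_index, .data$pattern, .data$gene_id),
    region = paste(sort(unique(.data$comparison)), collapse = ","),
    .groups = "drop")
  by_pattern <- dplyr::summarise(
    dplyr::group_by(regions, .data$pattern_index, .data$pattern, .data$region),
    count = dplyr::n(), .groups = "drop_last")
  by_pattern <- dplyr::ungroup(
    dplyr::mutate(by_pattern, fraction = .data$count / sum(.data$count)))
  summary <- dplyr::summarise(dplyr::group_by(regions, .data$region),
                              count = dplyr::n(), .groups = "drop")
  summary$fraction <- summary$count / sum(summary$count)
  list(by_pattern = by_pattern, summary = summary)
}
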