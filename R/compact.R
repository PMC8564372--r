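#' Build a COMPACT comparative matrix of pattern counts
#'
#' Crosses the control-referenced dynamic patterns of the two perturbation
#' arms over a common gene universe: cell (i, j) of the `3^T x 3^T` matrix
#' counts the genes whose DEAB pattern has index i (rows) and whose RA
#' pattern has index j (columns). With T = 4 time points this is the 81 x 81,
#' 6561-cell COMPACT grid.
#'
#' @param patterns_deab,patterns_ra Pattern tibbles from
#'   [discretize_patterns()] for the DEAB and RA comparisons, covering the
#'   same gene universe.
#' @return A `ra_compact` object: `counts` (dense integer matrix with pattern
#'   strings as dimnames), `cells` (long tibble: `deab_index`, `ra_index`,
#'   `deab_pattern`, `ra_pattern`, `count`, `gene_ids` list column, nonzero
#'   cells only), `t_len`, `n_genes`.
#' @export
build_compact <- function(patterns_deab, patterns_ra) {
  t_len <- unique(c(patterns_deab$t_len, patterns_ra$t_len))
  if (length(t_len) != 1) abort("pattern sets have different numbers of time points")
  if (!setequal(patterns_deab$gene_id, patterns_ra$gene_id) ||
      anyDuplicated(patterns_deab$gene_id) || anyDuplicated(patterns_ra$gene_id)) {
    abort("pattern sets must cover the same gene universe exactly once")
  }
  k <- 3^t_len
  labels <- vapply(0:(k - 1),
                   function(i) pattern_string(pattern_decode(i, t_len)),
                   character(1))
  pairs <- dplyr::inner_join(
    dplyr::select(patterns_deab, "gene_id", deab_index = "pattern_index"),
    dplyr::select(patterns_ra, "gene_id", ra_index = "pattern_index"),
    by = "gene_id")
  cells <- dplyr::summarise(
    dplyr::group_by(pairs, .data$deab_index, .data$ra_index),
    count = dplyr::n(), gene_ids = list(sort(.data$gene_id)),
    .groups = "drop")
  cells$deab_pattern <- labels[cells$deab_index + 1]
  cells$ra_pattern <- labels[cells$ra_index + 1]
  counts <- matrix(0L, k, k, dimnames = list(DEAB = labels, RA = labels))
  counts[cbind(cells$deab_index + 1, cells$ra_index + 1)] <- cells$count
  structure(
    list(counts = counts,
         cells = dplyr::select(cells, "deab_index", "ra_index",
                               "deab_pattern", "ra_pattern", "count",
                               "gene_ids"),
         t_len = t_len, n_genes = nrow(pairs)),
    class = "ra_compact")
}

#' @export
print.ra_compact <- function(x, ...) {
  cat(sprintf("COMPACT matrix: %d x %d patterns (T = %d), %d genes, %d occupied cells\n",
              nrow(x$counts), ncol(x$counts), x$t_len, x$n_genes,
              sum(x$counts > 0)))
  invisible(x)
}

#' Onset group of a ternary dynamic pattern
#'
#' Coarse label of a pattern by the time of its first nonzero call and that
#' call's direction; the all-zero pattern maps to `no-change`. Over the T = 4
#' grid this yields exactly 9 groups (1 + 4 times x 2 directions).
#'
#' @param values Pattern vector with entries in \{-1, 0, +1\}.
#' @param times Time labels for the pattern positions; defaults to the
#'   positions themselves.
#' @return A single label, e.g. `"1.5h-up"` or `"no-change"`.
#' @export
onset_group <- function(values, times = NULL) {
  if (!all(values %in% c(-1, 0, 1))) abort("pattern entries must be -1, 0 or +1")
  times <- times %||% seq_along(values)
  nz <- which(values != 0)
  if (length(nz) == 0) return("no-change")
  first <- nz[1]
  sprintf("%gh-%s", times[first], if (values[first] > 0) "up" else "down")
}

onset_levels <- function(t_len, times = NULL) {
  times <- times %||% seq_len(t_len)
  c("no-change",
    as.vector(t(outer(sprintf("%gh", times), c("up", "down"), paste, sep = "-"))))
}

#' Coarse-grain a COMPACT matrix by response onset
#'
#' Pools the fine `3^T x 3^T` grid by the onset group of the row and column
#' patterns, giving (for T = 4) a 9 x 9, 81-cell matrix whose total equals
#' the fine total.
#'
#' @param compact An `ra_compact` from [build_compact()].
#' @param times Time labels for the pattern positions (e.g.
#'   `c(0, 1.5, 3, 4.5)`); defaults to positions.
#' @return Integer matrix with onset-group dimnames (rows DEAB, columns RA).
#' @export
coarse_grain <- function(compact, times = NULL) {
  stopifnot(inherits(compact, "ra_compact"))
  t_len <- compact$t_len
  groups <- vapply(0:(3^t_len - 1),
                   function(i) onset_group(pattern_decode(i, t_len), times),
                   character(1))
  lev <- onset_levels(t_len, times)
  f <- factor(groups, levels = lev)
  rows_pooled <- rowsum(compact$counts, f)          # pool DEAB (row) patterns
  both_pooled <- t(rowsum(t(rows_pooled), f))       # pool RA (column) patterns
  out <- matrix(0L, length(lev), length(lev),
                dimnames = list(DEAB = lev, RA = lev))
  out[rownames(both_pooled), colnames(both_pooled)] <- both_pooled
  storage.mode(out) <- "integer"
  out
}

#' Classify each gene's joint response to the two RA perturbations
#'
#' The direction of a pattern is the sign of its first nonzero call (none for
#' the all-zero pattern). Genes are partitioned into: `non-responsive` (no
#' direction in either arm), `RA-only` / `DEAB-only` (one arm silent), and
#' the four COMPACT quadrants for doubly-responsive genes — `quadrant-a`
#' (up in both), `quadrant-b` (up on RA addition, down on DEAB knockdown: the
#' canonical reciprocal RA-target/metabolism signature), `quadrant-c` (the
#' mirror image) and `quadrant-d` (down in both). Mixed-sign patterns
#' (direction reversals after onset) are flagged.
#'
#' @param patterns_ra,patterns_deab Pattern tibbles from
#'   [discretize_patterns()] over the same gene universe.
#' @return Tibble: `gene_id`, `direction_ra`, `direction_deab` (-1/0/+1),
#'   `mixed_sign` (either pattern reverses direction), `category`.
#' @export
classify_response <- function(patterns_ra, patterns_deab) {
  t_len <- unique(c(patterns_ra$t_len, patterns_deab$t_len))
  if (length(t_len) != 1) abort("pattern sets have different numbers of time points")
  dir_of <- function(idx) {
    v <- pattern_decode(idx, t_len)
    nz <- v[v != 0]
    if (length(nz) == 0) 0L else as.integer(sign(nz[1]))
  }
  mixed_of <- function(idx) {
    v <- pattern_decode(idx, t_len)
    nz <- v[v != 0]
    length(unique(nz)) > 1
  }
  joined <- dplyr::inner_join(
    dplyr::select(patterns_ra, "gene_id", ra_index = "pattern_index"),
    dplyr::select(patterns_deab, "gene_id", deab_index = "pattern_index"),
    by = "gene_id")
  if (nrow(joined) != nrow(patterns_ra) || nrow(joined) != nrow(patterns_deab)) {
    abort("pattern sets must cover the same gene universe")
  }
  joined$direction_ra <- vapply(joined$ra_index, dir_of, integer(1))
  joined$direction_deab <- vapply(joined$deab_index, dir_of, integer(1))
  joined$mixed_sign <- vapply(joined$ra_index, mixed_of, logical(1)) |
    vapply(joined$deab_index, mixed_of, logical(1))
  joined$category <- dplyr::case_when(
    joined$direction_ra == 0 & joined$direction_deab == 0 ~ "non-responsive",
    joined$direction_deab == 0 ~ "RA-only",
    joined$direction_ra == 0 ~ "DEAB-only",
    joined$direction_ra > 0 & joined$direction_deab > 0 ~ "quadrant-a",
    joined$direction_ra > 0 & joined$direction_deab < 0 ~ "quadrant-b",
    joined$direction_ra < 0 & joined$direction_deab > 0 ~ "quadrant-c",
    TRUE ~ "quadrant-d")
  dplyr::select(joined, "gene_id", "direction_ra", "direction_deab",
                "mixed_sign", "category")
}
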