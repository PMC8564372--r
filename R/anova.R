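#' Per-gene two-way ANOVA significance gate
#'
#' Fits, for every gene, a fixed-effects two-way ANOVA of expression on time,
#' treatment and their interaction (clutches are the replicates), and flags
#' genes where any of the three effects is significant. The per-gene evidence
#' is the union test `p_union = min(1, 3 * min(p))` — the Bonferroni
#' combination over the three effects, which keeps the per-gene type-I rate
#' at its nominal level despite the selection over effects — and `p_union` is
#' then Benjamini-Hochberg adjusted across genes, so the gene-level false
#' discovery rate is controlled at `q_threshold`.
#'
#' The design must be balanced (equal clutch counts in every treatment x time
#' cell) with replication; the sums of squares are then computed in closed
#' form from cell means, vectorized over genes.
#'
#' @param expr Long expression tibble (log2 or normalized scale) with
#'   `treatment` and `time_h` metadata.
#' @param q_threshold BH-adjusted significance cutoff, default 0.05.
#' @return Tibble, one row per gene: `gene_id`, `p_time`, `p_treatment`,
#'   `p_interaction`, `p_min`, `p_union`, `q`, `significant`. Filter on
#'   `significant` (or `q <= q_threshold`) for the gene list.
#' @export
significance_filter <- function(expr, q_threshold = 0.05) {
  check_expression(expr)
  if (q_threshold < 0 || q_threshold > 1) abort("q_threshold must be in [0, 1]")
  m <- expr_matrix(expr)
  meta <- expr_metadata(expr)
  meta <- meta[match(colnames(m), meta$sample_id), ]
  res <- anova_two_way(m, factor(meta$time_h), factor(meta$treatment))
  res$p_min <- pmin(res$p_time, res$p_treatment, res$p_interaction)
  res$p_union <- pmin(1, 3 * res$p_min)
  res$q <- p.adjust(res$p_union, method = "BH")
  res$significant <- res$q <= q_threshold
  res
}

# closed-form balanced two-way ANOVA, vectorized over the rows of y
anova_two_way <- function(y, f_a, f_b) {
  cell <- interaction(f_a, f_b, drop = FALSE)
  counts <- table(cell)
  if (any(counts == 0)) abort("empty treatment x time cell")
  if (length(unique(as.integer(counts))) != 1) {
    abort("unbalanced design: unequal replication across treatment x time cells")
  }
  r <- as.integer(counts[1])
  a <- nlevels(f_a)
  b <- nlevels(f_b)
  n <- ncol(y)
  if (n - a * b <= 0) abort("no residual degrees of freedom (unreplicated cells)")

  group_means <- function(f) {
    ind <- stats::model.matrix(~ f - 1)
    sweep(y %*% ind, 2, colSums(ind), "/")
  }
  gm <- rowMeans(y)
  ma <- group_means(f_a)
  mb <- group_means(f_b)
  mab <- group_means(cell)

  ss_a <- b * r * rowSums((ma - gm)^2)
  ss_b <- a * r * rowSums((mb - gm)^2)
  ss_cells <- r * rowSums((mab - gm)^2)
  ss_ab <- pmax(ss_cells - ss_a - ss_b, 0)
  ss_tot <- rowSums((y - gm)^2)
  ss_res <- pmax(ss_tot - ss_cells, 0)

  df_a <- a - 1
  df_b <- b - 1
  df_ab <- df_a * df_b
  df_res <- n - a * b
  ms_res <- ss_res / df_res

  p_of <- function(ss, df) {
    unname(pf(ss / df / ms_res, df, df_res, lower.tail = FALSE))
  }
  tibble::tibble(
    gene_id = rownames(y),
    p_time = p_of(ss_a, df_a),
    p_treatment = p_of(ss_b, df_b),
    p_interaction = p_of(ss_ab, df_ab)
  )
}
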