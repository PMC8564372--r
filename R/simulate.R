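#' Noise-free and noisy expression kinetics for one gene in one clutch
#'
#' The generative model for a gene observed in one clutch under one treatment:
#' \deqn{y(t) = baseline + drift(t) + \delta(class, treatment) \cdot
#'       A(clutch, direction) \cdot 2^{-t / halftime} + \epsilon}
#' where `delta` is the planted response direction (+1/0/-1), `A` the clutch
#' feedback gain for that perturbation direction, and the exponential factor
#' models the post-washout recovery: deflections from control are maximal at
#' the washout (t = 0, where the magnitude equals the planted gain) and close
#' over the chase. Control samples have `delta = 0` by definition. The drift
#' term is the developmental trend shared by all treatment arms and so cancels
#' in any treatment-minus-control comparison.
#'
#' @param gene_class One of `r paste0('\x60', GENE_CLASSES, '\x60', collapse = ", ")`.
#' @param clutch_params List with `a_ra`, `a_deab` (gains, log2-units) and
#'   `halftime` (hours, positive).
#' @param treatment `"Control"`, `"RA"` or `"DEAB"`.
#' @param times Time grid including 0.
#' @param noise_sd Standard deviation of the additive log2 noise (0 for the
#'   noise-free kinetic).
#' @param baseline,drift_slope,drift_amplitude Baseline level and drift
#'   parametrization; drift is linear, `drift_amplitude * drift_slope * t /
#'   max(t)`.
#' @param sign_same Direction (+1 or -1) used for the `both_same` and
#'   `both_opposite` classes (for `both_opposite` it is the RA direction).
#' @return Numeric vector of expression values, one per time point.
#' @examples
#' simulate_profile("RA_only_up", list(a_ra = 2, a_deab = 2, halftime = 1.5),
#'                  "RA", times = c(0, 1.5, 3, 4.5), noise_sd = 0)
#' @export
simulate_profile <- function(gene_class, clutch_params, treatment, times,
                             noise_sd = 0, baseline = 0, drift_slope = 0,
                             drift_amplitude = 0, sign_same = 1) {
  if (!gene_class %in% GENE_CLASSES) {
    abort(paste0("unknown gene_class: ", gene_class))
  }
  if (clutch_params$halftime <= 0) abort("recovery halftime must be positive")
  if (!0 %in% times) abort("times must include 0")
  delta <- class_deltas(gene_class, sign_same)
  d <- switch(treatment, RA = delta[["delta_ra"]],
              DEAB = delta[["delta_deab"]], Control = 0,
              abort(paste0("unknown treatment: ", treatment)))
  gain <- switch(treatment, RA = clutch_params$a_ra,
                 DEAB = clutch_params$a_deab, Control = 0)
  tmax <- max(times)
  drift <- if (tmax > 0) drift_amplitude * drift_slope * times / tmax else 0
  y <- baseline + drift + d * gain * 2^(-times / clutch_params$halftime)
  if (noise_sd > 0) y <- y + rnorm(length(times), 0, noise_sd)
  y
}

# planted response directions (relative to control) per class
class_deltas <- function(gene_class, sign_same = 1) {
  switch(gene_class,
    null           = c(delta_ra = 0, delta_deab = 0),
    RA_only_up     = c(delta_ra = 1, delta_deab = 0),
    RA_only_down   = c(delta_ra = -1, delta_deab = 0),
    DEAB_only_up   = c(delta_ra = 0, delta_deab = 1),
    DEAB_only_down = c(delta_ra = 0, delta_deab = -1),
    both_same      = c(delta_ra = sign_same, delta_deab = sign_same),
    both_opposite  = c(delta_ra = sign_same, delta_deab = -sign_same)
  )
}

# deterministic class counts by largest remainder, over the free genes
class_counts <- function(proportions, n_free) {
  raw <- proportions * n_free
  counts <- floor(raw)
  short <- n_free - sum(counts)
  if (short > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1
  }
  counts
}

# gene table: built-in panel first (fixed classes), then the free genes
build_gene_table <- function(config) {
  sets <- ra_gene_sets()
  up_net <- ra_network_up_with_ra()
  panel <- tibble::tibble(
    gene_id = c(sets$hox, sets$ra_network, "gapdh.S"),
    class = c(rep("both_opposite", length(sets$hox) + length(sets$ra_network)),
              "null"),
    sign_same = c(rep(1, length(sets$hox)),
                  ifelse(sets$ra_network %in% up_net, 1, -1),
                  0)
  )
  n_free <- config$n_genes - nrow(panel)
  counts <- class_counts(config$class_proportions, n_free)
  free_classes <- sample(rep(names(counts), counts))
  free <- tibble::tibble(
    gene_id = sprintf("gene_%05d", seq_len(n_free)),
    class = free_classes,
    sign_same = sample(c(-1, 1), n_free, replace = TRUE)
  )
  genes <- dplyr::bind_rows(panel, free)
  deltas <- purrr::map2(genes$class, genes$sign_same,
                        function(cl, s) class_deltas(cl, if (s == 0) 1 else s))
  genes$delta_ra <- purrr::map_dbl(deltas, "delta_ra")
  genes$delta_deab <- purrr::map_dbl(deltas, "delta_deab")
  genes$baseline <- rnorm(nrow(genes), config$baseline_mean, config$baseline_sd)
  # responsive genes drift along their dominant response direction (RA target
  # genes rise over gastrulation); null genes get an arbitrary trend, the
  # housekeeping gene none at all
  genes$drift_slope <- ifelse(
    genes$delta_ra != 0, genes$delta_ra,
    ifelse(genes$delta_deab != 0, genes$delta_deab, rnorm(nrow(genes))))
  genes$drift_slope[genes$gene_id == "gapdh.S"] <- 0
  genes
}

build_clutch_table <- function(config) {
  decay_sum <- vapply(config$recovery_halftime_h,
                      function(h) sum(2^(-config$times_h / h)), numeric(1))
  cl <- tibble::tibble(
    clutch = config$clutch_ids,
    u = config$tradeoff_u,
    a_ra = config$gain_scale * config$tradeoff_u,
    a_deab = config$gain_scale * (1 - config$tradeoff_u),
    halftime = config$recovery_halftime_h,
    score_ra = .data$a_ra * decay_sum,
    score_deab = .data$a_deab * decay_sum
  )
  cl$rank_ra <- rank_with_id_ties(cl$score_ra, cl$clutch)
  cl$rank_deab <- rank_with_id_ties(cl$score_deab, cl$clutch)
  cl
}

rank_with_id_ties <- function(score, id) {
  match(seq_along(score), order(score, id))
}

#' Simulate a full multi-clutch RA perturbation study
#'
#' Generates one expression sample per (clutch, treatment, time) cell — with
#' the default design 12 clutches x 3 treatments x 4 time points = 144
#' samples — plus a matching qPCR Ct table for the RA network / hox gene panel
#' of the clutches assigned to the qPCR-like assay, and the planted ground
#' truth needed to validate every downstream stage. Clutches are split evenly
#' into an `rnaseq`-like and an `htqpcr`-like assay half. Output is
#' deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list of class `ra_sim`: `expression` (long tibble on the log2
#'   scale), `ct` (long Ct tibble, see [simulate_ct_table()]), `truth` (see
#'   Details) and `config`.
#' @details `truth$genes` holds the per-gene response class and planted
#'   directions; `truth$clutches` the per-clutch gains, trade-off parameter
#'   and true robustness ranks (rank 1 = most robust = smallest planted
#'   shift); `truth$deflection` the noise-free clutch-averaged
#'   treatment-minus-control deflection per gene, treatment and time, from
#'   which [truth_patterns()] derives the planted ternary patterns for any
#'   fold threshold.
#' @examples
#' sim <- simulate_dataset(sim_config(n_genes = 50, seed = 1))
#' dplyr::n_distinct(sim$expression$sample_id)
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  genes <- with_stream_seed(config$seed, "genes", build_gene_table(config))
  clutches <- build_clutch_table(config)

  meta <- tidyr::expand_grid(
    clutch = config$clutch_ids,
    treatment = config$treatments,
    time_h = config$times_h
  )
  meta$sample_id <- sprintf("%s_%s_%gh", meta$clutch, meta$treatment, meta$time_h)
  half <- ceiling(config$n_clutches / 2)
  meta$assay <- ifelse(match(meta$clutch, config$clutch_ids) <= half,
                       "rnaseq", "htqpcr")

  grid <- tidyr::expand_grid(gene_id = genes$gene_id, sample_id = meta$sample_id)
  grid <- dplyr::inner_join(grid, meta, by = "sample_id")
  grid <- dplyr::inner_join(
    grid,
    dplyr::select(genes, "gene_id", "delta_ra", "delta_deab",
                  "baseline", "drift_slope"),
    by = "gene_id")
  grid <- dplyr::inner_join(
    grid, dplyr::select(clutches, "clutch", "a_ra", "a_deab", "halftime"),
    by = "clutch")

  tmax <- max(config$times_h)
  delta <- ifelse(grid$treatment == "RA", grid$delta_ra,
                  ifelse(grid$treatment == "DEAB", grid$delta_deab, 0))
  gain <- ifelse(grid$treatment == "RA", grid$a_ra,
                 ifelse(grid$treatment == "DEAB", grid$a_deab, 0))
  grid$value <- grid$baseline +
    config$drift_amplitude * grid$drift_slope * grid$time_h / tmax +
    delta * gain * 2^(-grid$time_h / grid$halftime)
  if (config$noise_sd > 0) {
    grid$value <- grid$value +
      with_stream_seed(config$seed, "noise",
                       rnorm(nrow(grid), 0, config$noise_sd))
  }
  expression <- set_expr_scale(
    dplyr::select(grid, dplyr::all_of(EXPR_COLS)), "log2")

  # clutch-averaged noise-free deflection per gene x perturbation x time
  perturbations <- setdiff(config$treatments, "Control")
  mean_gain <- purrr::map(perturbations, function(trt) {
    a <- if (trt == "RA") clutches$a_ra else clutches$a_deab
    vapply(config$times_h, function(t)
      mean(a * 2^(-t / clutches$halftime)), numeric(1))
  })
  names(mean_gain) <- perturbations
  deflection <- tidyr::expand_grid(
    gene_id = genes$gene_id, treatment = perturbations,
    time_h = config$times_h)
  deflection <- dplyr::inner_join(
    deflection, dplyr::select(genes, "gene_id", "delta_ra", "delta_deab"),
    by = "gene_id")
  dd <- ifelse(deflection$treatment == "RA",
               deflection$delta_ra, deflection$delta_deab)
  gg <- purrr::map2_dbl(deflection$treatment,
                        match(deflection$time_h, config$times_h),
                        function(trt, i) mean_gain[[trt]][i])
  deflection$deflection <- dd * gg
  deflection <- dplyr::select(deflection, "gene_id", "treatment",
                              "time_h", "deflection")

  truth <- list(genes = genes, clutches = clutches, deflection = deflection)
  structure(list(expression = expression,
                 ct = simulate_ct_table(config, expression),
                 truth = truth, config = config),
            class = "ra_sim")
}

#' Simulate a high-throughput qPCR Ct table from expression values
#'
#' Emulates a Fluidigm-style run: each gene x sample of the qPCR-assay
#' clutches is measured in three pre-amplification groups (emulating the L/S
#' homeolog-specific and pan-gene primer pools) and three technical
#' replicates. `Ct = ct_intercept - log2_expression + jitter`, so one log2
#' unit of expression lowers Ct by exactly one cycle, and the housekeeping
#' gene (`gapdh.S`, constant by construction) has treatment-independent Ct.
#'
#' @param config A [sim_config()].
#' @param expression A long expression tibble on the log2 scale containing the
#'   RA network / hox panel and the housekeeping gene.
#' @return Long tibble: `gene_id`, `sample_id`, `clutch`, `treatment`,
#'   `time_h`, `preamp_group`, `tech_replicate`, `ct`, with attribute
#'   `housekeeping` = `"gapdh.S"`.
#' @export
simulate_ct_table <- function(config, expression) {
  check_expression(expression)
  panel <- c(unlist(ra_gene_sets(), use.names = FALSE), "gapdh.S")
  if (!"gapdh.S" %in% expression$gene_id) {
    abort("housekeeping gene gapdh.S missing from expression input")
  }
  base <- dplyr::filter(expression, .data$assay == "htqpcr",
                        .data$gene_id %in% panel)
  ct <- tidyr::expand_grid(preamp_group = 1:3, tech_replicate = 1:3)
  ct <- tidyr::crossing(base, ct)
  ct$ct <- config$ct_intercept - ct$value
  if (config$ct_jitter_sd > 0) {
    ct$ct <- ct$ct + with_stream_seed(config$seed, "ct",
                                      rnorm(nrow(ct), 0, config$ct_jitter_sd))
  }
  out <- dplyr::select(ct, "gene_id", "sample_id", "clutch", "treatment",
                       "time_h", "preamp_group", "tech_replicate", "ct")
  attr(out, "housekeeping") <- "gapdh.S"
  out
}

#' Planted ternary patterns implied by the simulation ground truth
#'
#' Applies the same ternary discretization rule as [discretize_patterns()] to
#' the noise-free clutch-averaged deflections stored in an `ra_sim` truth, so
#' noise-free runs of the full pattern pipeline can be checked for exact
#' agreement.
#'
#' @param truth The `truth` element of a [simulate_dataset()] result.
#' @param fold_threshold_linear Linear fold-change threshold (> 1).
#' @return Tibble: `gene_id`, `comparison`, `pattern`, `pattern_index`.
#' @export
truth_patterns <- function(truth, fold_threshold_linear = 1.3) {
  d <- dplyr::rename(truth$deflection, comparison = "treatment",
                     diff = "deflection")
  discretize_patterns(d, fold_threshold_linear)
}
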