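GENE_CLASSES <- c("null", "RA_only_up", "RA_only_down", "DEAB_only_up",
                  "DEAB_only_down", "both_same", "both_opposite")

#' Configuration for the synthetic pulse-chase experiment
#'
#' Describes a multi-clutch RA perturbation study: embryos from `n_clutches`
#' independent clutches are transiently treated (RA addition, DEAB inhibition
#' of RA synthesis, or control), washed, and profiled at the listed chase
#' times. Each clutch carries its own feedback gains `A_RA` and `A_DEAB`
#' (log2-units of initial deflection from control) derived from a trade-off
#' parameter `u` in `[0, 1]`: `A_RA = gain_scale * u` and
#' `A_DEAB = gain_scale * (1 - u)`, so robustness to increased versus
#' decreased RA is anti-correlated across clutches by construction.
#' Post-washout deflections decay exponentially with a clutch-specific
#' half-time.
#'
#' @param n_clutches Number of clutches (biological replicates); ids `A`, `B`,
#'   ... Must be at least 2.
#' @param treatments Treatment arms; the first entry is the reference arm.
#' @param times_h Chase time grid in hours, sorted, starting at 0 (washout).
#' @param n_genes Total number of genes, including the built-in RA network,
#'   hox and housekeeping panel (see [ra_gene_sets()]).
#' @param class_proportions Named fractions over the gene response classes
#'   `r paste0('\x60', GENE_CLASSES, '\x60', collapse = ", ")`; must sum to 1.
#'   Applied to the genes outside the built-in panel.
#' @param gain_scale Maximum initial deflection, log2-units.
#' @param tradeoff_u Per-clutch trade-off parameters in `[0, 1]`; default an
#'   even grid spanning `[0, 1]`.
#' @param recovery_halftime_h Per-clutch half-time (hours) of the post-washout
#'   decay of deflections; scalar values are recycled.
#' @param noise_sd Standard deviation of the per-measurement log2 noise.
#' @param drift_amplitude Amplitude (log2-units over the chase window) of the
#'   developmental drift shared by all clutches.
#' @param baseline_mean,baseline_sd Distribution of per-gene baseline
#'   expression, log2-units.
#' @param ct_intercept qPCR calibration: Ct of a gene at log2 expression 0.
#' @param ct_jitter_sd Standard deviation of the pre-amplification-group and
#'   technical-replicate Ct jitter, cycles.
#' @param seed Root seed; child streams (gene assignment, measurement noise,
#'   Ct jitter) are derived from it so stages can be re-run independently.
#' @return A `sim_config` list.
#' @examples
#' cfg <- sim_config(n_genes = 200, seed = 7)
#' cfg$times_h
#' @export
sim_config <- function(n_clutches = 12,
                       treatments = c("Control", "RA", "DEAB"),
                       times_h = c(0, 1.5, 3, 4.5),
                       n_genes = 2000,
                       class_proportions = c(
                         null = 0.70, RA_only_up = 0.05, RA_only_down = 0.05,
                         DEAB_only_up = 0.05, DEAB_only_down = 0.05,
                         both_same = 0.04, both_opposite = 0.06
                       ),
                       gain_scale = 2.4,
                       tradeoff_u = NULL,
                       recovery_halftime_h = 1.5,
                       noise_sd = 0.25,
                       drift_amplitude = 1,
                       baseline_mean = 8,
                       baseline_sd = 2,
                       ct_intercept = 24,
                       ct_jitter_sd = 0.15,
                       seed = 1) {
  if (n_clutches < 2) abort("n_clutches must be at least 2")
  if (times_h[1] != 0 || is.unsorted(times_h, strictly = TRUE)) {
    abort("times_h must be strictly increasing and start at 0")
  }
  if (!"Control" %in% treatments) abort("treatments must include 'Control'")
  if (is.null(names(class_proportions)) ||
      !all(names(class_proportions) %in% GENE_CLASSES)) {
    abort(paste("class_proportions must be named with classes among:",
                paste(GENE_CLASSES, collapse = ", ")))
  }
  if (abs(sum(class_proportions) - 1) > 1e-8) {
    abort("class_proportions must sum to 1")
  }
  panel_size <- length(unlist(ra_gene_sets())) + 1L # + housekeeping
  if (n_genes < panel_size + length(class_proportions)) {
    abort(sprintf("n_genes must be at least %d (gene panel + one gene per class)",
                  panel_size + length(class_proportions)))
  }
  if (is.null(tradeoff_u)) {
    # evenly spaced over [0, 1] but interleaved across the two assay halves,
    # so each assay spans the full robustness gradient (the observed clutch
    # robustness ordering intermingles RNA-seq and qPCR clutches)
    base <- seq(0, 1, length.out = n_clutches)
    half <- ceiling(n_clutches / 2)
    tradeoff_u <- numeric(n_clutches)
    tradeoff_u[seq_len(half)] <- base[seq(1, by = 2, length.out = half)]
    tradeoff_u[(half + 1):n_clutches] <-
      base[seq(2, by = 2, length.out = n_clutches - half)]
  }
  if (length(tradeoff_u) != n_clutches ||
      any(tradeoff_u < 0 | tradeoff_u > 1)) {
    abort("tradeoff_u must give one value in [0, 1] per clutch")
  }
  halftime <- rep_len(recovery_halftime_h, n_clutches)
  if (any(halftime <= 0)) abort("recovery_halftime_h must be positive")

  structure(
    list(
      n_clutches = as.integer(n_clutches),
      clutch_ids = make.unique(rep(LETTERS, length.out = n_clutches)),
      treatments = treatments,
      times_h = times_h,
      n_genes = as.integer(n_genes),
      class_proportions = class_proportions,
      gain_scale = gain_scale,
      tradeoff_u = tradeoff_u,
      recovery_halftime_h = halftime,
      noise_sd = noise_sd,
      drift_amplitude = drift_amplitude,
      baseline_mean = baseline_mean,
      baseline_sd = baseline_sd,
      ct_intercept = ct_intercept,
      ct_jitter_sd = ct_jitter_sd,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# derive a reproducible child seed for a named stream (kept below 2^31)
child_seed <- function(seed, stream) {
  offset <- c(genes = 101L, noise = 211L, ct = 307L)[[stream]]
  (as.numeric(seed) %% 1e6) * 1009 + offset
}

with_stream_seed <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(child_seed(seed, stream))
  expr
}
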