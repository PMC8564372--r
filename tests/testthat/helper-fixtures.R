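# small study configurations reused across tests

noise_free_config <- function(n_genes = 120, seed = 1, ...) {
  sim_config(n_genes = n_genes, seed = seed, noise_sd = 0, ct_jitter_sd = 0, ...)
}

small_config <- function(n_genes = 120, seed = 1, ...) {
  sim_config(n_genes = n_genes, seed = seed, ...)
}

# a minimal long expression tibble from a genes x samples matrix and a
# metadata data frame
expr_fixture <- function(m, meta, scale = "log2") {
  rarobust:::expr_from_matrix(m, tibble::as_tibble(meta), scale = scale)
}

# balanced design metadata: one sample per clutch x treatment x time
design_meta <- function(clutches = c("A", "B"),
                        treatments = c("Control", "RA", "DEAB"),
                        times = c(0, 1.5, 3, 4.5),
                        assay = "rnaseq") {
  g <- expand.grid(clutch = clutches, treatment = treatments, time_h = times,
                   stringsAsFactors = FALSE)
  g$sample_id <- sprintf("%s_%s_%gh", g$clutch, g$treatment, g$time_h)
  g$assay <- assay
  g[, c("sample_id", "clutch", "treatment", "time_h", "assay")]
}

# independent dense-search projection oracle: linearly interpolate the
# polyline at fine arc-length steps and take the nearest interpolated point
brute_force_projection <- function(point, vertices, step = 1e-4) {
  seg <- diff(vertices)
  len <- sqrt(rowSums(seg^2))
  total <- sum(len)
  grid <- seq(0, total, by = step)
  pts <- polyline_point(grid, vertices, len)
  d2 <- colSums((t(pts) - point)^2)
  best <- which.min(d2)
  # refine around the coarse optimum
  lo <- max(0, grid[best] - 2 * step)
  hi <- min(total, grid[best] + 2 * step)
  fine <- seq(lo, hi, length.out = 4001)
  pts <- polyline_point(fine, vertices, len)
  d2 <- colSums((t(pts) - point)^2)
  best <- which.min(d2)
  list(lambda = fine[best], sq_residual = d2[best])
}

polyline_point <- function(lambda, vertices, len) {
  cum <- c(0, cumsum(len))
  idx <- findInterval(lambda, cum, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1), length(len))
  frac <- (lambda - cum[idx]) / len[idx]
  vertices[idx, , drop = FALSE] + diff(vertices)[idx, , drop = FALSE] * frac
}
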