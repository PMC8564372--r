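test_that("PCA scores capture planted low-rank structure deterministically", {
  meta <- design_meta(clutches = LETTERS[1:3])
  n_s <- nrow(meta)
  set.seed(12)
  # planted 1-D trajectory: all genes load on one latent coordinate
  latent <- seq(-2, 2, length.out = n_s)
  loadings <- rnorm(8)
  m <- outer(loadings, latent) + matrix(rnorm(8 * n_s, sd = 0.05), 8)
  rownames(m) <- sprintf("g%d", 1:8)
  colnames(m) <- meta$sample_id
  expr <- expr_fixture(m, meta, scale = "zscore")
  sc <- pca_scores(expr, rownames(m))
  v <- attr(sc, "variance")
  expect_gte(sum(v) / sum(apply(m, 1, var)), 0.9)
  expect_gte(v[1] / sum(v), 0.9)

  # samples confined to a 2-plane: third component variance ~ 0
  m2 <- rbind(x = latent, y = latent^2, z = latent + latent^2)
  m2 <- m2 + 0   # exact plane: z = x + y
  rownames(m2) <- c("gx", "gy", "gz")
  colnames(m2) <- meta$sample_id
  sc2 <- pca_scores(expr_fixture(m2, meta, scale = "zscore"), rownames(m2))
  expect_lt(attr(sc2, "variance")[3], 1e-20)

  # deterministic sign: largest-magnitude loading positive
  rot <- attr(sc, "loadings")
  for (j in seq_len(ncol(rot))) {
    expect_gt(rot[which.max(abs(rot[, j])), j], 0)
  }
  expect_error(pca_scores(expr, c("g1", "g2")), "at least 3")
})

test_that("net shift follows the normalized lambda-difference formula", {
  lam_tbl <- function(ctrl, trt) {
    times <- c(0, 1.5, 3, 4.5)
    tibble::tibble(
      sample_id = sprintf("s%d", 1:8), clutch = "A",
      treatment = rep(c("Control", "RA"), each = 4),
      time_h = rep(times, 2), assay = "rnaseq",
      lambda = c(ctrl, trt), sq_residual = 0)
  }
  # identical treatment and control: s = 0
  sh0 <- expression_shift(lam_tbl(c(0, 1, 2, 3), c(0, 1, 2, 3)),
                          gene_set_label = "hox")
  expect_equal(unique(sh0$s), 0)

  # hand-evaluated example: four gaps of 0.5 with max lambda 3.5
  sh <- expression_shift(lam_tbl(c(0, 1, 2, 3), c(0.5, 1.5, 2.5, 3.5)),
                         gene_set_label = "hox")
  expect_equal(unique(sh$s), 4 * 0.5 / 3.5, tolerance = 1e-12)
  expect_equal(sh$d, rep(0.5 / 3.5, 4), tolerance = 1e-12)

  # invariance under uniform rescaling of the score space
  sh2 <- expression_shift(
    lam_tbl(2 * c(0, 1, 2, 3), 2 * c(0.5, 1.5, 2.5, 3.5)),
    gene_set_label = "hox")
  expect_equal(sh2$s, sh$s, tolerance = 1e-12)

  # missing cell is an error
  bad <- lam_tbl(c(0, 1, 2, 3), c(0.5, 1.5, 2.5, 3.5))[-2, ]
  expect_error(expression_shift(bad, gene_set_label = "hox"), "missing")
})

test_that("clutch ranking sorts ascending with id tie-break", {
  sh <- tibble::tibble(
    clutch = c("B", "A", "C"), treatment = "RA", gene_set = "hox",
    time_h = 0, d = 0, s = c(0.2, 0.5, 0.2))
  rk <- rank_clutches(sh, "hox", "RA")
  expect_equal(rk$clutch, c("B", "C", "A"))
  expect_equal(rk$rank, 1:3)
  expect_error(rank_clutches(sh, "hox", "DEAB"), "no shifts")
})

test_that("noise-free trajectory recovers the planted robustness order", {
  cfg <- noise_free_config(n_genes = 150, seed = 19)
  sim <- simulate_dataset(cfg)
  z_rna <- suppressWarnings(
    zscore_genes(dplyr::filter(sim$expression, .data$assay == "rnaseq")))
  z_q <- suppressWarnings(zscore_genes(delta_delta_ct(sim$ct)))
  comb <- combine_assays(z_rna, z_q)
  traj <- fit_trajectory(comb, ra_gene_sets()$hox, "hox")
  sh <- expression_shift(traj)
  for (trt in c("RA", "DEAB")) {
    rk <- rank_clutches(sh, "hox", trt)
    planted_col <- paste0("rank_", tolower(trt))
    planted <- sim$truth$clutches$clutch[order(sim$truth$clutches[[planted_col]])]
    expect_equal(rk$clutch, planted)
  }
  # control-vs-itself shift is identically zero by construction of the formula
  self <- dplyr::mutate(
    dplyr::filter(traj$lambda, .data$treatment == "Control"),
    treatment = "SelfControl")
  both <- dplyr::bind_rows(traj$lambda, self)
  s_self <- expression_shift(both, gene_set_label = "hox")
  expect_equal(unique(s_self$s[s_self$treatment == "SelfControl"]), 0)
})

test_that("efficiency-efficacy quadrants follow the median cutpoints", {
  mk_shift <- function(net, hox) {
    dplyr::bind_rows(
      tibble::tibble(clutch = LETTERS[seq_along(net)], treatment = "RA",
                     gene_set = "ra_network", time_h = 0, d = 0, s = net),
      tibble::tibble(clutch = LETTERS[seq_along(hox)], treatment = "RA",
                     gene_set = "hox", time_h = 0, d = 0, s = hox))
  }
  q <- efficiency_quadrants(mk_shift(c(0.1, 0.2, 0.8, 0.9),
                                     c(0.1, 0.9, 0.2, 0.9)))
  expect_equal(q$quadrant[q$clutch == "A"], "efficient-effective")
  expect_equal(q$quadrant[q$clutch == "B"], "ineffective")
  expect_equal(q$quadrant[q$clutch == "C"], "effective-inefficient")
  expect_equal(q$quadrant[q$clutch == "D"], "inefficient-ineffective")

  # degenerate: identical clutches all land in the low quadrant with a warning
  expect_warning(qd <- efficiency_quadrants(mk_shift(rep(0.5, 4), rep(0.5, 4))),
                 "degenerate")
  expect_equal(unique(qd$quadrant), "efficient-effective")
})

test_that("planted trade-off surfaces as anti-correlated hox shifts", {
  cfg <- noise_free_config(n_genes = 150, seed = 23)
  sim <- simulate_dataset(cfg)
  z_rna <- suppressWarnings(
    zscore_genes(dplyr::filter(sim$expression, .data$assay == "rnaseq")))
  z_q <- suppressWarnings(zscore_genes(delta_delta_ct(sim$ct)))
  comb <- combine_assays(z_rna, z_q)
  traj <- fit_trajectory(comb, ra_gene_sets()$hox, "hox")
  sh <- shift_summary(expression_shift(traj))
  wide <- tidyr::pivot_wider(sh, names_from = "treatment", values_from = "s")
  expect_lt(cor(wide$RA, wide$DEAB), 0)
})
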