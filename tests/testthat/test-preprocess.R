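meta2 <- design_meta(clutches = "A", treatments = c("Control", "RA"),
                     times = c(0, 1.5))

test_that("minimum-expression filter drops only genes low everywhere", {
  m <- rbind(all4 = rep(4, 4), spike = c(0, 0, 0, 5), high = rep(100, 4))
  colnames(m) <- meta2$sample_id
  expr <- expr_fixture(m, meta2, scale = "counts")

  kept <- unique(filter_min_expression(expr, 5)$gene_id)
  expect_setequal(kept, c("spike", "high"))

  # 10 all-zero genes among 100 leave 90
  m2 <- matrix(10, 100, 4, dimnames = list(sprintf("g%03d", 1:100),
                                           meta2$sample_id))
  m2[1:10, ] <- 0
  expr2 <- expr_fixture(m2, meta2, scale = "counts")
  expect_equal(dplyr::n_distinct(filter_min_expression(expr2, 5)$gene_id), 90)
  # gene order preserved
  expect_equal(unique(filter_min_expression(expr2, 5)$gene_id),
               sprintf("g%03d", 11:100))

  log_expr <- expr_fixture(m, meta2, scale = "log2")
  expect_error(filter_min_expression(log_expr, 5), "count-scale")
})

test_that("log2 transform applies the pseudocount convention", {
  m <- matrix(c(0, 7, 1023, 3), 1, 4,
              dimnames = list("g", meta2$sample_id))
  expr <- expr_fixture(m, meta2, scale = "counts")
  out <- log2_transform(expr, 1)
  expect_equal(out$value[match(meta2$sample_id, out$sample_id)],
               c(0, 3, 10, 2))
  expect_equal(rarobust:::expr_scale(out), "log2")
  m[1] <- -1
  expect_error(log2_transform(expr_fixture(m, meta2, scale = "counts")),
               "negative")
})

test_that("quantile normalization equalizes sample distributions", {
  meta_ab <- meta2[1:2, ]
  m <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2,
              dimnames = list(c("g1", "g2", "g3"), meta_ab$sample_id))
  expr <- expr_fixture(m, meta_ab)
  out <- expr_matrix(quantile_normalize(expr))
  expect_equal(unname(out[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(out[, 2]), c(2.5, 3.5, 4.5))

  # identical samples are a fixed point
  m_id <- matrix(rep(c(5, 1, 9), 4), 3, 4,
                 dimnames = list(c("g1", "g2", "g3"), meta2$sample_id))
  expr_id <- expr_fixture(m_id, meta2)
  expect_equal(expr_matrix(quantile_normalize(expr_id)), m_id)

  # defining invariant + rank preservation on random input
  set.seed(42)
  m_rand <- matrix(rnorm(200), 50, 4,
                   dimnames = list(sprintf("g%02d", 1:50), meta2$sample_id))
  out_rand <- expr_matrix(quantile_normalize(expr_fixture(m_rand, meta2)))
  sorted <- apply(out_rand, 2, sort)
  expect_lt(max(abs(sorted - sorted[, 1])), 1e-12)
  for (j in 1:4) expect_equal(rank(out_rand[, j]), rank(m_rand[, j]))

  one <- expr_fixture(m_rand[, 1, drop = FALSE], meta2[1, ])
  expect_error(quantile_normalize(one), "2 samples")
})

test_that("gene Z-scoring centers, scales, drops constants and is idempotent", {
  m <- rbind(g1 = c(1, 2, 3, 4), flat = c(5, 5, 5, 5))
  colnames(m) <- meta2$sample_id
  expr <- expr_fixture(m, meta2)
  expect_warning(z <- zscore_genes(expr), "constant")
  zm <- expr_matrix(z)
  expect_equal(rownames(zm), "g1")
  expect_equal(mean(zm), 0)
  expect_equal(sd(zm), 1)
  # idempotence
  z2 <- zscore_genes(z)
  expect_equal(expr_matrix(z2), zm)
  expect_equal(rarobust:::expr_scale(z2), "zscore")
})

test_that("delta-delta-Ct arithmetic and the pre-amp median rule", {
  # two samples, one gene + housekeeping; target 1 cycle lower in RA
  base <- expand.grid(gene_id = c("tgt", "gapdh.S"),
                      sample_id = c("A_Control_0h", "A_RA_0h"),
                      preamp_group = 1:3, tech_replicate = 1:3,
                      stringsAsFactors = FALSE)
  base$clutch <- "A"
  base$treatment <- ifelse(grepl("RA", base$sample_id), "RA", "Control")
  base$time_h <- 0
  base$ct <- ifelse(base$gene_id == "gapdh.S", 18,
                    ifelse(base$treatment == "RA", 24, 25))
  ct <- tibble::as_tibble(base)
  attr(ct, "housekeeping") <- "gapdh.S"
  out <- delta_delta_ct(ct)
  expect_equal(out$value[out$treatment == "Control"], 0)   # reference vs itself
  expect_equal(out$value[out$treatment == "RA"], 1)        # 1 cycle lower = +1 log2

  # median across pre-amp groups: {20, 21, 30} -> 21
  ct2 <- ct
  ct2$ct[ct2$gene_id == "tgt" & ct2$treatment == "RA"] <-
    rep(c(20, 21, 30), each = 3)
  out2 <- delta_delta_ct(ct2)
  expect_equal(out2$value[out2$treatment == "RA"], 25 - 21)

  expect_error(delta_delta_ct(dplyr::filter(ct, .data$gene_id != "gapdh.S")),
               "housekeeping")
  expect_error(delta_delta_ct(ct, reference_treatment = "DEAB"), "reference")
})

test_that("delta-delta-Ct inverts the Ct simulation at zero jitter", {
  cfg <- noise_free_config(seed = 9)
  sim <- simulate_dataset(cfg)
  rel <- delta_delta_ct(sim$ct)
  # planted relative log2 expression vs the clutch's Control 0 h sample
  qpcr <- dplyr::filter(sim$expression, .data$assay == "htqpcr",
                        .data$gene_id %in% unique(rel$gene_id))
  ref <- dplyr::filter(qpcr, .data$treatment == "Control", .data$time_h == 0)
  ref <- dplyr::select(ref, "gene_id", "clutch", ref_value = "value")
  truth <- dplyr::inner_join(qpcr, ref, by = c("gene_id", "clutch"))
  j <- dplyr::inner_join(rel, truth, by = c("gene_id", "sample_id"),
                         suffix = c("", ".t"))
  expect_equal(j$value, j$value.t - j$ref_value, tolerance = 1e-9)
})

test_that("assay combination restricts to shared genes and keeps values", {
  cfg <- noise_free_config(seed = 5)
  sim <- simulate_dataset(cfg)
  z_rna <- suppressWarnings(
    zscore_genes(dplyr::filter(sim$expression, .data$assay == "rnaseq")))
  z_q <- suppressWarnings(zscore_genes(delta_delta_ct(sim$ct)))
  comb <- combine_assays(z_rna, z_q)
  expect_equal(dplyr::n_distinct(comb$sample_id), 144)
  expect_setequal(unique(comb$gene_id),
                  intersect(unique(z_rna$gene_id), unique(z_q$gene_id)))

  # doubling a matrix under new sample ids duplicates columns
  z_b <- dplyr::mutate(z_rna, sample_id = paste0(.data$sample_id, "_dup"))
  z_b <- rarobust:::set_expr_scale(z_b, "zscore")
  both <- combine_assays(z_rna, z_b)
  expect_equal(dplyr::n_distinct(both$sample_id),
               2 * dplyr::n_distinct(z_rna$sample_id))

  z_other <- dplyr::mutate(z_b, gene_id = paste0(.data$gene_id, "_x"))
  z_other <- rarobust:::set_expr_scale(z_other, "zscore")
  expect_error(combine_assays(z_rna, z_other), "share no genes")
  expect_error(combine_assays(sim$expression, z_q), "Z-scored")
})
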