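test_that("clutch averaging is a plain mean, invariant to clutch order", {
  meta <- design_meta(clutches = c("A", "B"), treatments = "Control",
                      times = c(0, 1.5))
  m <- matrix(c(1, 1, 3, 3), 1, 4, dimnames = list("g", meta$sample_id))
  m[1, ] <- c(1, 3, 1, 3)   # A = 1, B = 3 at both times
  expr <- expr_fixture(m, meta)
  avg <- clutch_mean(expr)
  expect_equal(avg$value, c(2, 2))

  # single clutch: identity
  cols <- meta$clutch == "A"
  one <- expr_fixture(m[, cols, drop = FALSE], meta[cols, ])
  expect_equal(clutch_mean(one)$value, unname(m[1, cols]))

  # permuting rows leaves the mean unchanged
  expr_perm <- expr[rev(seq_len(nrow(expr))), ]
  expect_equal(clutch_mean(expr_perm), avg)
})

test_that("t0-referenced differentials subtract the washout level", {
  avg <- tibble::tibble(gene_id = "g", treatment = "RA",
                        time_h = c(0, 1.5, 3, 4.5), value = c(5, 7, 7, 4))
  d <- differential_vs_t0(avg)
  expect_equal(d$diff, c(2, 2, -1))
  expect_equal(d$time_h, c(1.5, 3, 4.5))

  flat <- dplyr::mutate(avg, value = 3)
  expect_equal(differential_vs_t0(flat)$diff, c(0, 0, 0))
  expect_error(differential_vs_t0(dplyr::filter(avg, .data$time_h != 0)),
               "t = 0")
})

test_that("control-referenced differentials subtract Control per time", {
  avg <- tidyr::expand_grid(gene_id = "g",
                            treatment = c("Control", "RA"),
                            time_h = c(0, 1.5, 3, 4.5))
  avg$value <- ifelse(avg$treatment == "Control", 1,
                      1 + c(1, 0, 0, 0))
  d <- differential_vs_control(avg)
  expect_equal(d$diff, c(1, 0, 0, 0))

  same <- dplyr::mutate(avg, value = 2)
  expect_equal(differential_vs_control(same)$diff, rep(0, 4))
  # self-comparison of Control is identically zero
  expect_equal(differential_vs_control(same, "Control")$diff, rep(0, 4))
  expect_error(
    differential_vs_control(dplyr::filter(avg, .data$treatment != "Control")),
    "Control")
})

test_that("ternary encoding is a bijection for T = 3 and T = 4", {
  for (t_len in c(3, 4)) {
    idx <- vapply(0:(3^t_len - 1), function(i) pattern_index(pattern_decode(i, t_len)),
                  numeric(1))
    expect_equal(idx, 0:(3^t_len - 1))
    strings <- vapply(0:(3^t_len - 1),
                      function(i) pattern_string(pattern_decode(i, t_len)),
                      character(1))
    expect_equal(length(unique(strings)), 3^t_len)
  }
  expect_equal(pattern_index(c(1, 0, -1)), 2 * 9 + 1 * 3 + 0)
  expect_error(pattern_index(c(2, 0, 0)), "entries")
  expect_error(pattern_decode(81, 4), "range")
})

test_that("discretization thresholds on the log2 scale with inclusive boundary", {
  d <- tibble::tibble(gene_id = "g", comparison = "RA",
                      time_h = c(1.5, 3, 4.5), diff = c(1.2, 0.1, -1.5))
  pat <- discretize_patterns(d, 2)
  expect_equal(pat$pattern, "+0-")
  expect_equal(pat$pattern_index, pattern_index(c(1, 0, -1)))

  # the boundary |d| = tau is a call
  d2 <- dplyr::mutate(d, diff = c(1, -1, 0.999))
  expect_equal(discretize_patterns(d2, 2)$pattern, "+-0")

  # all-zero profile lands on the all-zero pattern
  d3 <- tibble::tibble(gene_id = "g", comparison = "RA",
                       time_h = c(0, 1.5, 3, 4.5), diff = 0)
  expect_equal(discretize_patterns(d3, 1.3)$pattern_index,
               pattern_index(c(0, 0, 0, 0)))
  expect_error(discretize_patterns(d, 1), "exceed 1")
})

test_that("raising the fold threshold only moves calls toward zero", {
  set.seed(33)
  for (rep in 1:20) {
    d <- tibble::tibble(gene_id = "g", comparison = "RA",
                        time_h = c(0, 1.5, 3, 4.5),
                        diff = rnorm(4, sd = 1.5))
    lo <- pattern_decode(discretize_patterns(d, 1.3)$pattern_index, 4)
    hi <- pattern_decode(discretize_patterns(d, 2.6)$pattern_index, 4)
    expect_true(all(abs(hi) <= abs(lo) & (hi == 0 | hi == lo)))
  }
})

test_that("pattern counting is complete and conserves genes", {
  set.seed(8)
  n <- 57
  pats <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:n), comparison = "RA",
    pattern_index = sample(0:26, n, replace = TRUE), t_len = 3)
  pats$pattern <- vapply(pats$pattern_index,
                         function(i) pattern_string(pattern_decode(i, 3)),
                         character(1))
  tab <- count_patterns(pats)
  expect_equal(nrow(tab), 27)
  expect_equal(sum(tab$count), n)
  expect_equal(sum(lengths(tab$gene_ids)), n)
  mixed <- dplyr::bind_rows(pats, dplyr::mutate(pats[1, ], t_len = 4))
  expect_error(count_patterns(mixed), "mix")
})

test_that("pattern overlap separates shared from group-specific genes", {
  mk <- function(ids, comparison, idx) {
    tibble::tibble(gene_id = ids, comparison = comparison,
                   pattern_index = idx, t_len = 3,
                   pattern = pattern_string(pattern_decode(idx[1], 3)))
  }
  ids <- sprintf("g%02d", 1:10)
  same <- dplyr::bind_rows(mk(ids, "RA", 26), mk(ids, "DEAB", 26))
  ov <- pattern_overlap(same)
  expect_equal(ov$summary$region, "DEAB,RA")
  expect_equal(ov$summary$fraction, 1)

  disjoint <- dplyr::bind_rows(mk(ids[1:5], "RA", 26), mk(ids[6:10], "DEAB", 26))
  ov2 <- pattern_overlap(disjoint)
  expect_setequal(ov2$summary$region, c("RA", "DEAB"))
  expect_equal(sum(ov2$summary$fraction), 1)

  # planted 20% shared
  mix <- dplyr::bind_rows(mk(ids[1:6], "RA", 26), mk(ids[5:10], "DEAB", 26))
  ov3 <- pattern_overlap(mix)
  shared <- ov3$summary$fraction[ov3$summary$region == "DEAB,RA"]
  expect_equal(shared, 0.2)
})

test_that("noise-free simulation reproduces planted patterns exactly", {
  cfg <- noise_free_config(n_genes = 150, seed = 13)
  sim <- simulate_dataset(cfg)
  avg <- clutch_mean(sim$expression)
  for (fold in c(1.3, 2)) {
    pat <- discretize_patterns(differential_vs_control(avg), fold)
    tp <- truth_patterns(sim$truth, fold)
    j <- dplyr::inner_join(pat, tp, by = c("gene_id", "comparison"))
    expect_equal(nrow(j), 2 * cfg$n_genes)
    expect_equal(mean(j$pattern_index.x == j$pattern_index.y), 1)
  }
})
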