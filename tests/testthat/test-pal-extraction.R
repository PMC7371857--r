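# Active-gene filter, z-scoring, SVD PAL extraction (Gram-matrix oracle),
# and bootstrap f_p p-values.

test_that("F-test filter keeps signal, drops constants, is calibrated on null", {
  d <- test_design(replicates = 3)
  pal <- sin(d$timepoints_h / 12)
  tr0 <- make_truth(d, pal, 3, noise_sd = 0, seed = 2)
  sig <- simulate_pathway_dataset(d, tr0, 3, 0)
  expect_setequal(filter_active_genes(sig), sig$gene_ids)

  const <- expression_dataset(matrix(5, 2, ncol(sig$values)),
                              sig$timepoints_h, sig$replicate_index)
  expect_length(filter_active_genes(const), 0)

  # Monte-Carlo calibration: 1e4 null genes retained at ~alpha
  trn <- make_truth(d, pal, 1, noise_sd = 1, seed = 3)
  nul <- simulate_pathway_dataset(d, trn, 1, 10000)
  kept <- filter_active_genes(nul, alpha = 0.05)
  frac <- sum(grepl("^null_", kept)) / 10000
  expect_gt(frac, 0.04)
  expect_lt(frac, 0.06)

  one_rep <- expression_dataset(matrix(rnorm(10), 2, 5), 1:5, rep(1, 5))
  expect_error(filter_active_genes(one_rep),
               class = "paldyn_degenerate_design")
})

test_that("z-scoring standardizes replicate-averaged profiles", {
  ds <- coherent_dataset(n_signal = 5, n_null = 5, noise_sd = 0.1)
  z <- zscore_profiles(ds)
  expect_equal(unname(rowMeans(z)), rep(0, nrow(z)), tolerance = 1e-12)
  expect_equal(unname(apply(z, 1, sd)), rep(1, nrow(z)), tolerance = 1e-12)

  # forced example: profile (1, 2, 3) -> (-1, 0, 1)
  d3 <- expression_dataset(rbind(a = c(1, 1, 2, 2, 3, 3), b = rep(5, 6)),
                           rep(1:3, each = 2), rep(1:2, 3))
  expect_warning(z3 <- zscore_profiles(d3), "zero temporal SD")
  expect_equal(unname(z3["a", ]), c(-1, 0, 1))
  expect_false("b" %in% rownames(z3))
})

test_that("PAL extraction agrees with the Gram-matrix eigen-oracle", {
  set.seed(101)
  x <- matrix(rnorm(30), 6, 5)
  dec <- pathway_activity(x)
  # oracle: eigen-decomposition of the 5x5 Gram matrix t(X) X
  eg <- eigen(crossprod(x), symmetric = TRUE)
  expect_equal(dec$f_p, eg$values / sum(eg$values), tolerance = 1e-9)
  mz <- colMeans(x)
  for (k in 1:5) {
    v <- eg$vectors[, k]
    if (sum(v * mz) < 0) v <- -v          # same sign convention
    expect_equal(dec$pal[, k], v, tolerance = 1e-9)
  }
  expect_equal(sum(dec$f_p), 1, tolerance = 1e-12)
  expect_equal(unname(colSums(dec$pal^2)), rep(1, 5), tolerance = 1e-9)
})

test_that("rank-1 and symmetric matrices give the expected f_p", {
  prof <- sin(seq(0, 3, length.out = 7))
  x <- outer(c(1, 2, -0.5, 0.8), prof)
  dec <- pathway_activity(x)
  expect_equal(dec$f_p[1], 1, tolerance = 1e-12)
  expect_equal(abs(cor(dec$pal[, 1], prof)), 1, tolerance = 1e-9)

  expect_equal(pathway_activity(diag(2))$f_p, c(0.5, 0.5))
  expect_error(pathway_activity(matrix(1, 1, 5)),
               class = "paldyn_insufficient_coverage")
})

test_that("PAL extraction is invariant to gene order and row sign flips", {
  set.seed(7)
  x <- matrix(rnorm(60), 10, 6)
  a <- pathway_activity(x)
  b <- pathway_activity(x[sample(10), ])
  expect_equal(abs(a$pal), abs(b$pal), tolerance = 1e-9)
  expect_equal(a$f_p, b$f_p, tolerance = 1e-12)
  flip <- x; flip[3, ] <- -flip[3, ]
  cc <- pathway_activity(flip)
  expect_equal(cc$f_p, a$f_p, tolerance = 1e-12)
  expect_equal(abs(cc$pal[, 1]), abs(a$pal[, 1]), tolerance = 1e-9)
})

test_that("coherent pathways attain the minimum bootstrap p-value", {
  d <- test_design()
  # noise-free signal + noisy pool: embed by building a combined dataset
  tr <- make_truth(d, sin(d$timepoints_h / 15), 10, noise_sd = 0, seed = 1)
  sig <- simulate_pathway_dataset(d, tr, 10, 0)
  trn <- make_truth(d, rep(0, 17), 1, noise_sd = 1, seed = 2)
  nul <- simulate_pathway_dataset(d, trn, 1, 200)
  comb <- expression_dataset(rbind(sig$values, nul$values[-1, ]),
                             sig$timepoints_h, sig$replicate_index,
                             c(sig$gene_ids, nul$gene_ids[-1]))
  ps <- pal_significance(sprintf("sig_%03d", 1:10), comb,
                         n_boot = 200, seed = 5)
  expect_equal(ps$f_p[1], 1, tolerance = 1e-12)
  expect_equal(ps$f_p_pvalue[1], 1 / 201)

  expect_error(pal_significance(sprintf("sig_%03d", 1:10), comb, n_boot = 50),
               class = "paldyn_usage_error")
})

test_that("the pathway significance rule combines f_c and f_p gates", {
  fake_cov <- function(p) structure(list(f_c_pvalue = p), class = "coverage_stats")
  fake_sig <- list(f_p = c(0.5, 0.2, 0.3), f_p_pvalue = c(0.03, 0.04, 0.9))
  r <- significant_pathways(fake_cov(0.01), fake_sig)
  expect_true(r$significant)
  expect_identical(r$sig_ranks, 1:2)
  expect_equal(r$total_fp, 0.7)
  expect_false(significant_pathways(fake_cov(0.2), fake_sig)$significant)
  fake_ns <- list(f_p = 0.9, f_p_pvalue = 0.5)
  expect_false(significant_pathways(fake_cov(0.01), fake_ns)$significant)
})
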