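# Synthetic-data generator: design grids, signal/null structure, noise
# calibration, fixture round-trips.

test_that("make_design reproduces the canonical sacrifice grids", {
  d <- make_design("acute", 17, 72, replicates = rep(3, 17), seed = 1)
  expect_length(d$timepoints_h, 17)
  expect_equal(max(d$timepoints_h), 72)
  expect_true(all(diff(d$timepoints_h) > 0))
  expect_gte(d$timepoints_h[1], 0)
  # dense early sampling: more than half the points inside the first 12 h
  expect_gt(sum(d$timepoints_h <= 12), 8)

  dc <- make_design("chronic", 11, 170, replicates = rep(4, 11), seed = 1)
  expect_length(dc$timepoints_h, 11)
  expect_equal(max(dc$timepoints_h), 170)

  expect_error(make_design("acute", 2, 72), class = "paldyn_invalid_design")
  expect_error(make_design("acute", 17, -1), class = "paldyn_invalid_design")
  expect_error(make_design("acute", 17, 72, replicates = rep(0, 17)),
               class = "paldyn_invalid_design")
})

test_that("zero-noise signal genes reproduce pal_true exactly", {
  d <- test_design()
  pal <- cos(d$timepoints_h / 10)
  tr <- make_truth(d, pal, n_signal_genes = 1, noise_sd = 0, seed = 3,
                   loading_range = c(1, 1))
  ds <- simulate_pathway_dataset(d, tr, 1, 0)
  rs <- replicate_stats(ds)
  expect_equal(unname(rs$mean[1, ]), pal, tolerance = 1e-12)
  # every replicate column too
  for (j in seq_along(ds$timepoints_h))
    expect_equal(ds$values[1, j], pal[match(ds$timepoints_h[j], d$timepoints_h)])
})

test_that("noisy signal genes track pal_true (r > 0.95 at noise_sd 0.05)", {
  d <- test_design()
  pal <- sin(d$timepoints_h / 12)
  tr <- make_truth(d, pal, n_signal_genes = 20, noise_sd = 0.05, seed = 7)
  ds <- simulate_pathway_dataset(d, tr, 20, 0)
  rs <- replicate_stats(ds)
  r <- apply(rs$mean, 1, function(g) cor(g, pal))
  expect_true(all(r > 0.95))
})

test_that("generator is seed-deterministic and seed-sensitive", {
  d <- test_design()
  tr <- make_truth(d, sin(d$timepoints_h / 10), 5, noise_sd = 0.1, seed = 11)
  a <- simulate_pathway_dataset(d, tr, 5, 5)
  b <- simulate_pathway_dataset(d, tr, 5, 5)
  expect_identical(a$values, b$values)
  tr2 <- make_truth(d, sin(d$timepoints_h / 10), 5, noise_sd = 0.1, seed = 12)
  c2 <- simulate_pathway_dataset(d, tr2, 5, 5)
  expect_false(identical(a$values, c2$values))
})

test_that("null-gene noise SD matches noise_sd within 10% at n >= 1e4", {
  d <- test_design(replicates = 4)
  tr <- make_truth(d, sin(d$timepoints_h / 10), 1, noise_sd = 0.2, seed = 5)
  n_null <- ceiling(1e4 / (17 * 4))
  ds <- simulate_pathway_dataset(d, tr, 1, n_null)
  nul <- ds$values[grepl("^null_", ds$gene_ids), ]
  expect_gt(length(nul), 1e4)
  expect_lt(abs(sd(as.numeric(nul)) - 0.2) / 0.2, 0.10)
})

test_that("dimension mismatch between truth and design raises a shape error", {
  d <- test_design()
  d2 <- make_design("chronic", replicates = 3)
  tr <- make_truth(d, rep(1, 17), 3, seed = 1)
  expect_error(simulate_pathway_dataset(d2, tr, 3, 0),
               class = "paldyn_shape_error")
  expect_error(simulate_pathway_dataset(d, tr, 4, 0),
               class = "paldyn_shape_error")
})

test_that("fixture bundle round-trips losslessly", {
  d <- test_design()
  tr <- make_truth(d, sin(d$timepoints_h / 9), 6, noise_sd = 0.07, seed = 9)
  ds <- simulate_pathway_dataset(d, tr, 6, 4)
  pws <- list(pathway_definition("pw1", "signal", sprintf("sig_%03d", 1:6)),
              pathway_definition("pw2", "noise", sprintf("null_%03d", 1:4)))
  out <- withr::local_tempdir()
  paths <- write_fixture_bundle(ds, pws, tr, out)

  ds2 <- read_expression_tsv(paths[["expression"]])
  expect_equal(ds2$values, ds$values, tolerance = 1e-12)
  expect_equal(ds2$timepoints_h, ds$timepoints_h)
  expect_identical(ds2$gene_ids, ds$gene_ids)

  expect_identical(length(readLines(paths[["gmt"]])), length(pws))
  pws2 <- read_gmt(paths[["gmt"]])
  expect_identical(pws2$pw1$gene_ids, pws[[1]]$gene_ids)

  tr2 <- read_truth_json(paths[["truth"]])
  expect_identical(tr2$seed, tr$seed)
  expect_equal(tr2$pal_true, tr$pal_true, tolerance = 1e-12)
  expect_equal(tr2$gene_loadings, tr$gene_loadings, tolerance = 1e-12)
})
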