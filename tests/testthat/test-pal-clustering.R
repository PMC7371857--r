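# Bootstrap PAL ensembles, gap-statistic cluster-number choice, k-means
# centroids with SD bands.

test_that("degenerate replicate noise reproduces the original PAL", {
  d <- test_design(replicates = 2)
  tr <- make_truth(d, sin(d$timepoints_h / 15), 6, noise_sd = 0, seed = 4)
  sig <- simulate_pathway_dataset(d, tr, 6, 0)
  trn <- make_truth(d, rep(0, 17), 1, noise_sd = 1, seed = 5)
  nul <- simulate_pathway_dataset(d, trn, 1, 60)
  comb <- expression_dataset(rbind(sig$values, nul$values[-1, ]),
                             sig$timepoints_h, sig$replicate_index,
                             c(sig$gene_ids, nul$gene_ids[-1]))
  # zero replicate SD for the pathway genes -> every bootstrap PAL equals
  # the original rank-1 PAL
  ens <- bootstrap_pal_ensemble(sprintf("sig_%03d", 1:6), comb,
                                n_boot = 25, seed = 2, n_null = 100)
  expect_gte(nrow(ens), 25)
  orig <- pathway_activity(zscore_profiles(subset_genes(comb,
                            sprintf("sig_%03d", 1:6))))
  r1 <- ens[attr(ens, "ranks") == 1, , drop = FALSE]
  for (i in seq_len(nrow(r1)))
    expect_equal(unname(r1[i, ]), unname(orig$pal[, 1]), tolerance = 1e-9)

  ens2 <- bootstrap_pal_ensemble(sprintf("sig_%03d", 1:6), comb,
                                 n_boot = 25, seed = 2, n_null = 100)
  expect_identical(ens, ens2)  # fixed seed -> identical ensemble
})

test_that("noisy bootstrap ensembles stay near the original PAL", {
  ds <- coherent_dataset(n_signal = 8, n_null = 100, noise_sd = 0.15)
  ens <- bootstrap_pal_ensemble(sprintf("sig_%03d", 1:8), ds, n_boot = 40,
                                seed = 3, n_null = 100)
  expect_gt(nrow(ens), 10)
  orig <- pathway_activity(zscore_profiles(subset_genes(ds,
                             sprintf("sig_%03d", 1:8))))
  r1 <- ens[attr(ens, "ranks") == 1, , drop = FALSE]
  cors <- apply(r1, 1, cor, y = orig$pal[, 1])
  expect_gt(median(abs(cors)), 0.9)
})

test_that("gap statistic finds two separated bundles and one tight bundle", {
  x <- two_bundles(seed = 3)
  expect_identical(as.integer(choose_k_gap(x, k_max = 4, seed = 1)), 2L)

  single <- two_bundles(seed = 4)[1:30, ]
  expect_identical(as.integer(choose_k_gap(single, k_max = 3, seed = 1)), 1L)

  ident <- matrix(rep(1:5, each = 10), 10)
  expect_identical(as.integer(choose_k_gap(ident, k_max = 3, seed = 1)), 1L)
  expect_identical(as.integer(choose_k_gap(ident[1, , drop = FALSE],
                                           k_max = 1, seed = 1)), 1L)
  expect_error(choose_k_gap(ident[1:2, ], k_max = 5),
               class = "paldyn_bounds_error")
})

test_that("k-means centroids and SD bands summarize the bundles", {
  x <- two_bundles(n_each = 40, seed = 6, spread = 0.02)
  cl1 <- cluster_centroids(x, 1, seed = 1)
  expect_length(cl1, 1)
  expect_equal(cl1[[1]]$centroid, colMeans(x), tolerance = 1e-12)
  expect_identical(cl1[[1]]$n, 80L)

  cl2 <- cluster_centroids(x, 2, seed = 1)
  sizes <- vapply(cl2, `[[`, 1L, "n")
  expect_setequal(sizes, c(40L, 40L))
  for (cl in cl2) {
    memb <- if (sum(abs(cl$centroid - colMeans(x[1:40, ]))) <
                sum(abs(cl$centroid - colMeans(x[41:80, ])))) x[1:40, ]
            else x[41:80, ]
    sem <- apply(memb, 2, sd) / sqrt(nrow(memb))
    expect_true(all(abs(cl$centroid - colMeans(memb)) <= 2 * sem + 1e-12))
    expect_true(all(cl$sd >= 0))
  }

  # inertia nesting: W(k = 2) <= W(k = 1)
  w1 <- sum(sweep(x, 2, colMeans(x))^2)
  assign2 <- apply(x, 1, function(r)
    which.min(c(sum((r - cl2[[1]]$centroid)^2),
                sum((r - cl2[[2]]$centroid)^2))))
  w2 <- sum((x - t(vapply(assign2, function(j) cl2[[j]]$centroid,
                          numeric(ncol(x)))))^2)
  expect_lte(w2, w1)
})

test_that("cluster SD bands shrink as replicate noise vanishes", {
  d <- test_design(replicates = 3)
  mean_sd <- vapply(c(0.2, 0.1, 0.05, 0), function(ns) {
    tr <- make_truth(d, sin(d$timepoints_h / 15), 8, noise_sd = ns, seed = 8)
    sig <- simulate_pathway_dataset(d, tr, 8, 0)
    trn <- make_truth(d, rep(0, 17), 1, noise_sd = 1, seed = 9)
    nul <- simulate_pathway_dataset(d, trn, 1, 80)
    comb <- expression_dataset(rbind(sig$values, nul$values[-1, ]),
                               sig$timepoints_h, sig$replicate_index,
                               c(sig$gene_ids, nul$gene_ids[-1]))
    ens <- bootstrap_pal_ensemble(sprintf("sig_%03d", 1:8), comb,
                                  n_boot = 30, seed = 10, n_null = 100)
    r1 <- ens[attr(ens, "ranks") == 1, , drop = FALSE]
    cl <- cluster_centroids(r1, 1, seed = 1)
    mean(cl[[1]]$sd)
  }, 1.0)
  expect_true(all(diff(mean_sd) <= 1e-12))
  expect_lt(mean_sd[4], mean_sd[1])
})
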