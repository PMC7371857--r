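# Shared fixtures, all generated in code.

# small acute-like design with fixed replication (fast default for tests)
test_design <- function(replicates = 3, regimen = "acute") {
  make_design(regimen, replicates = replicates, seed = 1)
}

# a dataset holding one coherent pathway (sig_* genes on a shared smooth
# trajectory) embedded in a pool of null genes
coherent_dataset <- function(design = test_design(), n_signal = 10,
                             n_null = 200, noise_sd = 0.1, seed = 42,
                             pal_true = NULL) {
  if (is.null(pal_true))
    pal_true <- sin(design$timepoints_h / 15) * exp(-design$timepoints_h / 40)
  tr <- make_truth(design, pal_true, n_signal_genes = n_signal,
                   noise_sd = noise_sd, seed = seed)
  simulate_pathway_dataset(design, tr, n_signal, n_null)
}

# cached DRN trajectories under the canonical regimens
.drn_cache <- new.env(parent = emptyenv())
regimen_drn <- function(regimen = c("acute", "chronic")) {
  regimen <- match.arg(regimen)
  if (is.null(.drn_cache[[regimen]])) {
    reg <- dose_regimen(regimen)
    tt <- sort(unique(c(seq(0, reg$horizon_h, length.out = 721),
                        seq(0, 2, length.out = 101))))
    rec <- simulate_receptor(receptor_params(regimen),
                             pk_forcing(pk_params(regimen), reg), tt)
    .drn_cache[[regimen]] <- data.frame(time = rec$time, DRN = rec$DRN)
  }
  .drn_cache[[regimen]]
}

# fast stage budgets for fitting tests (full defaults are for real runs)
fast_fit_control <- list(sa_evals = 500, ps_evals = 300, grad_maxit = 100)

# two well-separated bundles of unit-norm profiles (between-centroid
# distance ~10x within-bundle SD)
two_bundles <- function(n_each = 30, nt = 17, seed = 1, spread = 0.02) {
  with_seed(seed, {
    t0 <- seq(0, 1, length.out = nt)
    c1 <- sin(2 * pi * t0); c1 <- c1 / sqrt(sum(c1^2))
    c2 <- cos(2 * pi * t0); c2 <- c2 / sqrt(sum(c2^2))
    x <- rbind(matrix(rep(c1, each = n_each), n_each) +
                 matrix(rnorm(n_each * nt, 0, spread), n_each),
               matrix(rep(c2, each = n_each), n_each) +
                 matrix(rnorm(n_each * nt, 0, spread), n_each))
    x / sqrt(rowSums(x^2))
  })
}
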