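# Synthetic expression data with the statistical structure PAL extraction
# assumes: signal genes are noisy loadings on a shared ground-truth pathway
# activity trajectory; null genes are pure replicate noise.

#' Construct a synthetic ground truth
#'
#' Signal genes are generated as `loading_i * pal_true(t) + noise`; loadings
#' are drawn uniformly on `loading_range` and a fraction
#' `anticorrelated_frac` of them get a negative sign (an "anti-correlated
#' subgroup", useful for testing codominant PALs).
#'
#' @param design a [make_design()] object.
#' @param pal_true numeric vector on `design$timepoints_h`, or a function of
#'   time (hours) evaluated on the design grid.
#' @param n_signal_genes number of coherent signal genes.
#' @param noise_sd per-observation Gaussian SD (>= 0). Default 0.1: roughly
#'   10% of the unit-scale trajectory amplitude, a realistic within-animal
#'   replicate spread for z-scale microarray profiles.
#' @param seed integer seed.
#' @param anticorrelated_frac fraction of loadings given negative sign.
#' @param loading_range range of |loading|.
#' @return object of class `synthetic_truth` with fields `pal_true`,
#'   `gene_loadings`, `null_gene_ids` (filled by
#'   [simulate_pathway_dataset()]), `noise_sd`, `seed`.
#' @export
make_truth <- function(design, pal_true, n_signal_genes = 20,
                       noise_sd = 0.1, seed = 1L,
                       anticorrelated_frac = 0, loading_range = c(0.5, 1.5)) {
  stopifnot(inherits(design, "study_design"), n_signal_genes >= 1,
            noise_sd >= 0)
  if (is.function(pal_true)) pal_true <- pal_true(design$timepoints_h)
  pal_true <- as.numeric(pal_true)
  if (length(pal_true) != length(design$timepoints_h) || !all(is.finite(pal_true)))
    paldyn_stop("paldyn_shape_error",
                "pal_true must be finite and defined on the design timepoints")
  loadings <- with_seed(seed, {
    l <- runif(n_signal_genes, loading_range[1], loading_range[2])
    flip <- runif(n_signal_genes) < anticorrelated_frac
    l[flip] <- -l[flip]
    l
  })
  structure(list(pal_true = pal_true, gene_loadings = loadings,
                 null_gene_ids = character(), noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' Simulate a pathway expression dataset
#'
#' Each signal gene observation is
#' `g_i(t, r) = loading_i * pal_true(t) + eps`, `eps ~ N(0, noise_sd^2)`
#' i.i.d. per observation; null genes are pure noise.  Reproducible under
#' the truth's seed.
#'
#' @param design a [make_design()] object.
#' @param truth a [make_truth()] object.
#' @param n_signal_genes number of signal genes; must match
#'   `length(truth$gene_loadings)`.
#' @param n_null_genes number of noise-only genes.
#' @return an [expression_dataset()]; signal genes are named `sig_###`,
#'   null genes `null_###`.
#' @export
#' @examples
#' d <- make_design("acute", replicates = 3)
#' tr <- make_truth(d, sin(d$timepoints_h / 10), n_signal_genes = 5,
#'                  noise_sd = 0, seed = 2)
#' simulate_pathway_dataset(d, tr, 5, 10)
simulate_pathway_dataset <- function(design, truth, n_signal_genes,
                                     n_null_genes = 0) {
  stopifnot(inherits(design, "study_design"), inherits(truth, "synthetic_truth"))
  if (length(truth$pal_true) != length(design$timepoints_h))
    paldyn_stop("paldyn_shape_error",
                "truth and design disagree on the number of timepoints")
  if (length(truth$gene_loadings) != n_signal_genes)
    paldyn_stop("paldyn_shape_error",
                "truth holds ", length(truth$gene_loadings),
                " loadings but n_signal_genes = ", n_signal_genes)
  reps <- design$replicates_per_timepoint
  tp_col <- rep(design$timepoints_h, reps)
  rep_col <- unlist(lapply(reps, seq_len), use.names = FALSE)
  n_obs <- length(tp_col)
  pal_col <- rep(truth$pal_true, reps)

  values <- with_seed(truth$seed, {
    sig <- outer(truth$gene_loadings, pal_col) +
      matrix(rnorm(n_signal_genes * n_obs, 0, truth$noise_sd),
             n_signal_genes, n_obs)
    if (n_null_genes > 0) {
      nul <- matrix(rnorm(n_null_genes * n_obs, 0, truth$noise_sd),
                    n_null_genes, n_obs)
      rbind(sig, nul)
    } else sig
  })
  ids <- c(sprintf("sig_%03d", seq_len(n_signal_genes)),
           if (n_null_genes > 0) sprintf("null_%03d", seq_len(n_null_genes)))
  expression_dataset(values, tp_col, rep_col, ids)
}

#' Simulate time-responsive but incoherent background genes
#'
#' Each gene gets its own independent random temporal profile (i.i.d.
#' `N(0, profile_sd^2)` per timepoint) plus replicate noise, so the genes
#' pass an across-time F-test (they are "active") yet share no common
#' structure.  This is the appropriate null pool for PAL significance:
#' differential-expression filtering retains such genes in real data, and
#' random subsets of them carry no dominant singular direction.
#'
#' @param design a [make_design()] object.
#' @param n_genes number of background genes.
#' @param profile_sd SD of each gene's own temporal profile (default 1,
#'   the z-score scale).
#' @param noise_sd replicate noise SD.
#' @param seed integer seed.
#' @param prefix gene-id prefix (default `"bg"`).
#' @return an [expression_dataset()].
#' @export
simulate_incoherent_genes <- function(design, n_genes, profile_sd = 1,
                                      noise_sd = 0.1, seed = 1L,
                                      prefix = "bg") {
  stopifnot(inherits(design, "study_design"), n_genes >= 1)
  reps <- design$replicates_per_timepoint
  nt <- length(design$timepoints_h)
  tp_col <- rep(design$timepoints_h, reps)
  rep_col <- unlist(lapply(reps, seq_len), use.names = FALSE)
  values <- with_seed(seed, {
    base <- matrix(rnorm(n_genes * nt, 0, profile_sd), n_genes, nt)
    base[, rep(seq_len(nt), reps)] +
      matrix(rnorm(n_genes * length(tp_col), 0, noise_sd), n_genes)
  })
  expression_dataset(values, tp_col, rep_col,
                     sprintf("%s_%04d", prefix, seq_len(n_genes)))
}

#' Write / read a synthetic fixture bundle
#'
#' Writes `expression.tsv` (see [write_expression_tsv()]), `pathways.gmt`
#' and `truth.json` under `out_dir`; the files round-trip losslessly through
#' [read_expression_tsv()], [read_gmt()] and [read_truth_json()].
#'
#' @param dataset an `expression_dataset`.
#' @param pathways list of pathway definitions (see [read_gmt()]).
#' @param truth a `synthetic_truth`.
#' @param out_dir output directory (created if missing).
#' @return named character vector of the three file paths.
#' @export
write_fixture_bundle <- function(dataset, pathways, truth, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    paldyn_stop("paldyn_io_error", "cannot create directory: ", out_dir)
  paths <- c(expression = file.path(out_dir, "expression.tsv"),
             gmt = file.path(out_dir, "pathways.gmt"),
             truth = file.path(out_dir, "truth.json"))
  write_expression_tsv(dataset, paths[["expression"]])
  write_gmt(pathways, paths[["gmt"]])
  jsonlite::write_json(unclass(truth), paths[["truth"]],
                       auto_unbox = TRUE, digits = NA, null = "null")
  paths
}

#' @rdname write_fixture_bundle
#' @param path path to a `truth.json` file.
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(pal_true = as.numeric(x$pal_true),
                 gene_loadings = as.numeric(x$gene_loadings),
                 null_gene_ids = as.character(x$null_gene_ids %||% character()),
                 noise_sd = as.numeric(x$noise_sd),
                 seed = as.integer(x$seed)),
            class = "synthetic_truth")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
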