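# PAL extraction: active-gene filtering, z-scoring, SVD decomposition of
# pathway gene x timepoint matrices into pathway activity levels (PALs) with
# fraction-of-variability f_p, and bootstrap f_p p-values.

#' Filter active (time-responsive) genes
#'
#' Retains genes whose one-way across-time ANOVA F-test p-value is at most
#' `alpha`.  This is a deliberately simple stand-in for a dedicated
#' time-course differential-expression tool; it only supplies the "active
#' gene" set the pathway analysis starts from.
#'
#' @param dataset an [expression_dataset()] with at least 2 replicates at at
#'   least 2 timepoints.
#' @param alpha retention threshold on the F-test p-value (default 0.05).
#' @return character vector of retained gene ids.  Constant (zero-variance)
#'   genes are never retained; zero within-timepoint variance with
#'   between-timepoint signal yields p = 0 and retention.
#' @export
filter_active_genes <- function(dataset, alpha = 0.05) {
  stopifnot(inherits(dataset, "expression_dataset"))
  tp <- dataset_timepoints(dataset)
  grp <- match(dataset$timepoints_h, tp)
  n <- tabulate(grp, nbins = length(tp))
  if (sum(n >= 2) < 2)
    paldyn_stop("paldyn_degenerate_design",
                "need >= 2 replicates at >= 2 timepoints for the F-test")
  N <- ncol(dataset$values); k <- length(tp)
  v <- dataset$values
  gm <- rowMeans(v)
  sums <- t(rowsum(t(v), grp))
  means <- sweep(sums, 2, n, "/")
  ssb <- rowSums(sweep((means - gm)^2, 2, n, "*"))
  sst <- rowSums((v - gm)^2)
  ssw <- pmax(sst - ssb, 0)
  Fstat <- (ssb / (k - 1)) / (ssw / (N - k))
  p <- pf(Fstat, k - 1, N - k, lower.tail = FALSE)
  # constant genes: 0/0 -> NaN -> excluded; zero-noise signal: Inf -> p = 0
  p[ssb == 0] <- 1
  p[is.nan(p)] <- 1
  dataset$gene_ids[p <= alpha]
}

#' Replicate-average and z-score gene profiles
#'
#' Replicates are averaged per timepoint, then each gene's temporal profile
#' is standardized to mean 0 and sample SD 1 (n-1 denominator) across
#' timepoints.  Genes with zero temporal SD cannot be standardized and are
#' dropped with a warning.
#'
#' @param dataset an [expression_dataset()].
#' @return numeric matrix (genes x timepoints) of z-scored profiles, row
#'   names = gene ids, with attribute `timepoints_h`.
#' @export
zscore_profiles <- function(dataset) {
  rs <- replicate_stats(dataset)
  m <- rs$mean
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  bad <- s == 0 | !is.finite(s)
  if (any(bad)) {
    warning(sum(bad), " gene(s) with zero temporal SD dropped: ",
            paste(head(rownames(m)[bad], 5), collapse = ", "),
            if (sum(bad) > 5) ", ...")
    m <- m[!bad, , drop = FALSE]; mu <- mu[!bad]; s <- s[!bad]
  }
  z <- (m - mu) / s
  attr(z, "timepoints_h") <- rs$timepoints_h
  z
}

#' Pathway activity levels by singular value decomposition
#'
#' Decomposes a z-scored pathway gene x timepoint matrix.  The k-th PAL is
#' the k-th right singular vector (a unit-norm temporal profile); the
#' fraction of pathway variability it captures is
#' `f_p(k) = sigma_k^2 / sum_j sigma_j^2`.  The SVD sign ambiguity is
#' resolved by forcing each PAL's inner product with the pathway's mean
#' z-scored profile to be non-negative (ties: first nonzero PAL element
#' made positive).
#'
#' @param z numeric matrix, genes x timepoints (>= 2 genes, >= 2 timepoints),
#'   e.g. a row subset of [zscore_profiles()] output.
#' @return object of class `pal_decomposition`: list with `pal`
#'   (timepoints x rank matrix of unit-norm PALs, descending singular value),
#'   `f_p`, `singular_values`, `timepoints_h`.
#' @export
pathway_activity <- function(z) {
  z <- as.matrix(z)
  if (nrow(z) < 2)
    paldyn_stop("paldyn_insufficient_coverage",
                "need >= 2 member genes with data, got ", nrow(z))
  if (ncol(z) < 2)
    paldyn_stop("paldyn_insufficient_coverage",
                "need >= 2 timepoints, got ", ncol(z))
  s <- svd(z)
  fp <- s$d^2 / sum(s$d^2)
  pal <- s$v
  mz <- colMeans(z)
  for (k in seq_len(ncol(pal))) {
    ip <- sum(pal[, k] * mz)
    if (ip < 0) pal[, k] <- -pal[, k]
    else if (ip == 0) {
      nz <- which(pal[, k] != 0)[1]
      if (!is.na(nz) && pal[nz, k] < 0) pal[, k] <- -pal[, k]
    }
  }
  tp <- attr(z, "timepoints_h")
  if (is.null(tp) && !is.null(colnames(z)))
    tp <- suppressWarnings(as.numeric(sub("^t", "", colnames(z))))
  if (is.null(tp) || anyNA(tp)) tp <- seq_len(ncol(z))
  structure(list(pal = pal, f_p = fp, singular_values = s$d,
                 timepoints_h = tp),
            class = "pal_decomposition")
}

# internal: null f_p distribution from random same-size gene sets.
# Returns n_boot x n_rank matrix of f_p values.
.fp_null <- function(z, size, n_boot, seed) {
  n_rank <- min(size, ncol(z))
  with_seed(seed, {
    t(vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(nrow(z), size)
      d <- svd(z[idx, , drop = FALSE], nu = 0, nv = 0)$d
      fp <- d^2 / sum(d^2)
      fp[seq_len(n_rank)]
    }, numeric(n_rank)))
  })
}

#' Bootstrap f_p p-values for a pathway's PALs
#'
#' The null distribution of `f_p(k)` is built from `n_boot` random gene sets
#' of the same size drawn (without replacement) from the full filtered
#' dataset; `p(k)` is the add-one-corrected fraction of null draws whose
#' rank-k `f_p` is at least the observed one, so `p` lies in
#' `[1/(n_boot+1), 1]`.
#'
#' @param pathway_gene_ids member gene ids (only those present in `dataset`
#'   are used; >= 2 required).
#' @param dataset an [expression_dataset()] of all filtered genes, or a
#'   pre-computed [zscore_profiles()] matrix.
#' @param n_boot number of null draws (>= 100).
#' @param seed integer seed.
#' @return list with `f_p` (observed), `f_p_pvalue` (per rank), `pal`
#'   (the observed `pal_decomposition`), `n_boot`, `n_genes`.
#' @export
pal_significance <- function(pathway_gene_ids, dataset, n_boot = 1000, seed = 1L) {
  if (n_boot < 100)
    paldyn_stop("paldyn_usage_error", "n_boot must be >= 100, got ", n_boot)
  z <- if (is.matrix(dataset)) dataset else zscore_profiles(dataset)
  idx <- rownames(z) %in% pathway_gene_ids
  m <- sum(idx)
  if (m > nrow(z))
    paldyn_stop("paldyn_sampling_error", "pathway larger than dataset")
  zi <- z[idx, , drop = FALSE]
  attr(zi, "timepoints_h") <- attr(z, "timepoints_h")
  dec <- pathway_activity(zi)
  n_rank <- min(m, ncol(z))
  null_fp <- .fp_null(z, m, n_boot, seed)
  pv <- vapply(seq_len(n_rank), function(k)
    (1 + sum(null_fp[, k] >= dec$f_p[k])) / (n_boot + 1), 1.0)
  list(f_p = dec$f_p, f_p_pvalue = pv, pal = dec,
       n_boot = n_boot, n_genes = m)
}

#' Pathway significance rule
#'
#' A pathway is significant iff its coverage p-value is at most `alpha_fc`
#' and at least one PAL has `f_p` p-value at most `alpha_fp`.  Significant
#' ranks are taken sequentially from rank 1 (stopping at the first
#' non-significant rank), the standard way to test leading singular
#' components: testing every rank marginally and firing on "any rank"
#' would inflate the pathway-level false-positive rate far above
#' `alpha_fp`, since a pathway offers as many ranks as timepoints.  With
#' the sequential rule the pathway-level rate equals the rank-1 rate,
#' which is calibrated.  Also returns the total fraction of pathway
#' activity carried by the significant PALs.
#'
#' @param coverage a [coverage_stats()] object (with `f_c_pvalue` set).
#' @param pal_sig a [pal_significance()] result.
#' @param alpha_fc,alpha_fp significance thresholds (default 0.05 each).
#' @return list with `significant` (logical), `sig_ranks` (integer vector,
#'   a prefix `1:m` or empty), `total_fp` (sum of `f_p` over significant
#'   ranks).
#' @export
significant_pathways <- function(coverage, pal_sig,
                                 alpha_fc = 0.05, alpha_fp = 0.05) {
  stopifnot(is.finite(coverage$f_c_pvalue))
  sig_ranks <- leading_significant_ranks(pal_sig$f_p_pvalue, alpha_fp)
  list(significant = coverage$f_c_pvalue <= alpha_fc && length(sig_ranks) > 0,
       sig_ranks = sig_ranks,
       total_fp = sum(pal_sig$f_p[sig_ranks]))
}

#' Leading significant PAL ranks
#'
#' The ranks `1..m` where `m` is the last rank before the first
#' non-significant `f_p` p-value (possibly empty).
#'
#' @param p_values per-rank f_p p-values (rank order).
#' @param alpha_fp threshold.
#' @return integer vector, a prefix of the ranks.
#' @export
leading_significant_ranks <- function(p_values, alpha_fp = 0.05) {
  sig <- p_values <= alpha_fp
  m <- match(FALSE, sig, nomatch = length(sig) + 1L) - 1L
  seq_len(m)
}
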