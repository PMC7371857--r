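# Bootstrap PAL ensembles from replicate variability, k-means clustering
# with k-means++ seeding, and gap-statistic selection of the cluster number.

#' Bootstrap ensemble of significant PAL profiles
#'
#' Each of the `n_boot` bootstraps resamples every gene's per-timepoint value
#' from a normal distribution about its replicate mean with the replicate SD
#' (timepoints with a single replicate use the gene's pooled SD across
#' timepoints), re-runs PAL extraction on the resampled pathway matrix, and
#' retains the leading PALs whose `f_p` passes the significance gate
#' (sequentially from rank 1, see [leading_significant_ranks()]).  The gate
#' compares each bootstrap `f_p(k)` against one null `f_p` distribution
#' computed once from random same-size gene sets of the original dataset
#' (statistically equivalent to re-deriving the null per bootstrap, and far
#' cheaper).  The deterministic PAL sign convention is applied before
#' pooling.
#'
#' @param pathway_gene_ids member gene ids.
#' @param dataset [expression_dataset()] of all filtered genes (the sampling
#'   pool for the null).
#' @param n_boot number of bootstrapped gene sets (study default 1000).
#' @param seed integer seed.
#' @param alpha_fp significance threshold on the bootstrap f_p p-value.
#' @param n_null null draws for the f_p gate (>= 100).
#' @return matrix of retained PAL profiles (rows, unit norm) x timepoints,
#'   with attributes `ranks` (PAL rank of each row), `n_boot`,
#'   `timepoints_h`.
#' @export
bootstrap_pal_ensemble <- function(pathway_gene_ids, dataset, n_boot = 1000,
                                   seed = 1L, alpha_fp = 0.05, n_null = 200) {
  stopifnot(inherits(dataset, "expression_dataset"), n_boot >= 1)
  rs <- replicate_stats(dataset)
  keep <- rownames(rs$mean) %in% pathway_gene_ids
  if (sum(keep) < 2)
    paldyn_stop("paldyn_insufficient_coverage",
                "fewer than 2 pathway genes present in the dataset")
  m <- rs$mean[keep, , drop = FALSE]
  s <- rs$sd[keep, , drop = FALSE]
  # pooled fallback for single-replicate timepoints
  pooled <- apply(s, 1, function(x) {
    x <- x[is.finite(x)]
    if (length(x) == 0) NA_real_ else sqrt(mean(x^2))
  })
  for (j in seq_len(ncol(s))) {
    miss <- !is.finite(s[, j])
    s[miss, j] <- pooled[miss]
  }
  if (any(!is.finite(s)))
    paldyn_stop("paldyn_variance_model_error",
                "no replicate SD available for some gene(s) and no pooled fallback")

  z_full <- zscore_profiles(dataset)
  null_fp <- .fp_null(z_full, sum(keep), n_null, seed + 1L)
  tp <- rs$timepoints_h
  ng <- nrow(m); nt <- ncol(m)

  profs <- list(); ranks <- integer()
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      x <- m + matrix(rnorm(ng * nt), ng, nt) * s
      mu <- rowMeans(x); sdv <- apply(x, 1, sd)
      ok <- sdv > 0
      if (sum(ok) < 2) next
      zb <- (x[ok, , drop = FALSE] - mu[ok]) / sdv[ok]
      attr(zb, "timepoints_h") <- tp
      dec <- pathway_activity(zb)
      n_rank <- min(length(dec$f_p), ncol(null_fp))
      pv <- vapply(seq_len(n_rank), function(k)
        (1 + sum(null_fp[, k] >= dec$f_p[k])) / (nrow(null_fp) + 1), 1.0)
      for (k in leading_significant_ranks(pv, alpha_fp)) {
        profs[[length(profs) + 1L]] <- dec$pal[, k]
        ranks[length(ranks) + 1L] <- k
      }
    }
  })
  out <- if (length(profs)) do.call(rbind, profs) else
    matrix(numeric(), 0, nt)
  colnames(out) <- paste0("t", tp)
  attr(out, "ranks") <- ranks
  attr(out, "n_boot") <- n_boot
  attr(out, "timepoints_h") <- tp
  out
}

# internal: k-means with k-means++ seeding and multiple restarts, best
# inertia kept.  Returns a stats::kmeans fit or NULL if k non-empty clusters
# are unattainable.
.km_pp <- function(x, k, nstart = 20, iter_max = 100) {
  n <- nrow(x)
  if (k >= n) {
    cl <- seq_len(n)
    return(list(cluster = cl, centers = x, tot.withinss = 0,
                size = rep(1L, n)))
  }
  best <- NULL
  for (r in seq_len(nstart)) {
    centers <- matrix(0, k, ncol(x))
    centers[1, ] <- x[sample.int(n, 1), ]
    if (k > 1) {
      mind2 <- rowSums(sweep(x, 2, centers[1, ])^2)
      for (j in 2:k) {
        centers[j, ] <- if (sum(mind2) == 0) x[sample.int(n, 1), ]
                        else x[sample.int(n, 1, prob = mind2), ]
        mind2 <- pmin(mind2, rowSums(sweep(x, 2, centers[j, ])^2))
      }
    }
    fit <- tryCatch(
      kmeans(x, centers = centers, iter.max = iter_max),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  best
}

#' Choose the number of PAL clusters by the gap statistic
#'
#' Tibshirani's gap statistic with `n_reference` uniform reference sets
#' drawn over the data's principal-axis-aligned bounding box.  Picks the
#' smallest `k` with `Gap(k) >= Gap(k+1) - s(k+1)`.
#'
#' @param profiles matrix of profiles (rows) x timepoints.
#' @param k_max maximum clusters considered (default 4).
#' @param n_reference reference draws B (default 50).
#' @param seed integer seed.
#' @param nstart k-means restarts per fit.
#' @return chosen integer `k`, with attribute `gap` (the Gap curve) and
#'   `s` (its standard errors).
#' @export
choose_k_gap <- function(profiles, k_max = 4, n_reference = 50, seed = 1L,
                         nstart = 20) {
  x <- as.matrix(profiles)
  n <- nrow(x)
  if (k_max < 1) paldyn_stop("paldyn_usage_error", "k_max must be >= 1")
  if (k_max > n)
    paldyn_stop("paldyn_bounds_error", "k_max (", k_max,
                ") exceeds the number of profiles (", n, ")")
  if (n == 1) return(1L)
  ctr <- colMeans(x)
  tot_ss <- sum(sweep(x, 2, ctr)^2)
  if (tot_ss < 1e-18) return(1L)  # all profiles identical
  k_max <- min(k_max, n)

  logW <- function(y, k) {
    if (k == 1) w <- sum(sweep(y, 2, colMeans(y))^2)
    else {
      fit <- .km_pp(y, k, nstart = nstart)
      if (is.null(fit)) return(NA_real_)
      w <- fit$tot.withinss
    }
    log(max(w, 1e-300))
  }

  # PCA-aligned bounding box for the reference distribution
  xc <- sweep(x, 2, ctr)
  V <- svd(xc, nu = 0)$v
  xp <- xc %*% V
  lo <- apply(xp, 2, min); hi <- apply(xp, 2, max)

  with_seed(seed, {
    obs <- vapply(seq_len(k_max), function(k) logW(x, k), 1.0)
    ref <- matrix(NA_real_, n_reference, k_max)
    for (b in seq_len(n_reference)) {
      zp <- vapply(seq_along(lo), function(j) runif(n, lo[j], hi[j]),
                   numeric(n))
      zb <- zp %*% t(V)
      ref[b, ] <- vapply(seq_len(k_max), function(k) logW(zb, k), 1.0)
    }
    gap <- colMeans(ref) - obs
    sk <- apply(ref, 2, sd) * sqrt(1 + 1 / n_reference)
    k_hat <- k_max
    for (k in seq_len(k_max - 1)) {
      if (is.finite(gap[k]) && is.finite(gap[k + 1]) &&
          gap[k] >= gap[k + 1] - sk[k + 1]) { k_hat <- k; break }
    }
    structure(as.integer(k_hat), gap = gap, s = sk)
  })
}

#' Cluster PAL profiles and summarize centroids with SD bands
#'
#' k-means (k-means++ seeding, `nstart` restarts, best inertia).  Each
#' cluster is summarized by its centroid (member mean) and the per-timepoint
#' SD of its members — the error band drawn about PAL cluster centroids.
#' If `k` non-empty clusters cannot be formed (e.g. fewer distinct profiles
#' than `k`), `k` is reduced with a warning.
#'
#' @param profiles matrix of profiles (rows) x timepoints.
#' @param k number of clusters (<= number of profiles).
#' @param seed integer seed.
#' @param nstart k-means restarts.
#' @param pathway_id optional label attached to each cluster.
#' @return list of `pal_cluster` objects: `centroid`, `sd` (per timepoint),
#'   `n` (member count), `pathway_id`.
#' @export
cluster_centroids <- function(profiles, k, seed = 1L, nstart = 20,
                              pathway_id = NA_character_) {
  x <- as.matrix(profiles)
  if (k > nrow(x))
    paldyn_stop("paldyn_bounds_error", "k exceeds the number of profiles")
  fit <- with_seed(seed, {
    f <- .km_pp(x, k, nstart = nstart)
    while (is.null(f) && k > 1) {
      k <- k - 1
      warning("empty cluster persisted; reducing k to ", k)
      f <- .km_pp(x, k, nstart = nstart)
    }
    f
  })
  lapply(seq_len(k), function(j) {
    memb <- x[fit$cluster == j, , drop = FALSE]
    sdv <- if (nrow(memb) > 1) apply(memb, 2, sd) else rep(0, ncol(memb))
    structure(list(centroid = colMeans(memb), sd = sdv, n = nrow(memb),
                   pathway_id = pathway_id,
                   timepoints_h = attr(profiles, "timepoints_h")),
              class = "pal_cluster")
  })
}
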