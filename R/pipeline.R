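# End-to-end orchestration: expression TSV + GMT -> active-gene filter ->
# coverage -> PAL extraction + significance -> bootstrap ensembles ->
# clustering -> PK/receptor simulation -> model fitting -> response
# classification -> per-pathway JSON and a summary TSV.

#' Build a pipeline configuration
#'
#' @param expression path to an expression TSV (see
#'   [read_expression_tsv()]) or an [expression_dataset()].
#' @param gmt path to a GMT file or a list of [pathway_definition()]s.
#' @param regimen `"acute"` or `"chronic"` (selects dosing, PK and receptor
#'   parameter defaults).
#' @param out_dir output directory.
#' @param alpha_fc,alpha_fp significance thresholds (defaults 0.05).
#' @param alpha_filter active-gene F-test threshold (default 0.05).
#' @param n_boot bootstrap replicates for f_p p-values and PAL ensembles
#'   (study default 1000; must be >= 100).
#' @param k_max maximum clusters for the gap statistic (default 4).
#' @param min_measured minimum measured members for a pathway to stay in
#'   the analysis (low fractional occupancy gives inconclusive Fisher
#'   p-values; default 3).
#' @param seed integer master seed; every stochastic stage derives its own
#'   seed from it.
#' @param pk,receptor,dose optional [pk_params()], [receptor_params()],
#'   [dose_regimen()] overrides.
#' @param fit_control control list passed to [fit_pal_model()].
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(expression, gmt, regimen = c("acute", "chronic"),
                            out_dir = tempfile("paldyn_"),
                            alpha_fc = 0.05, alpha_fp = 0.05,
                            alpha_filter = 0.05,
                            n_boot = 1000, k_max = 4, min_measured = 3,
                            seed = 1L, pk = NULL, receptor = NULL,
                            dose = NULL, fit_control = list()) {
  regimen <- match.arg(regimen)
  for (a in c(alpha_fc, alpha_fp, alpha_filter))
    if (!is.numeric(a) || a <= 0 || a >= 1)
      paldyn_stop("paldyn_validation_error", "thresholds must lie in (0, 1)")
  if (n_boot < 100)
    paldyn_stop("paldyn_validation_error", "n_boot must be >= 100")
  structure(list(expression = expression, gmt = gmt, regimen = regimen,
                 out_dir = out_dir, alpha_fc = alpha_fc, alpha_fp = alpha_fp,
                 alpha_filter = alpha_filter, n_boot = n_boot, k_max = k_max,
                 min_measured = min_measured, seed = as.integer(seed),
                 pk = pk %||% pk_params(regimen),
                 receptor = receptor %||% receptor_params(regimen),
                 dose = dose %||% dose_regimen(regimen),
                 fit_control = fit_control),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' Recognized fields mirror the [pipeline_config()] arguments; `pk`,
#' `receptor` and `dose` may be objects of named parameter values.
#'
#' @param path JSON file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  regimen <- x$regimen %||% "acute"
  pk <- if (!is.null(x$pk)) do.call(pk_params, c(list(regimen), x$pk))
  rp <- if (!is.null(x$receptor))
    do.call(receptor_params, c(list(regimen), x$receptor))
  dz <- if (!is.null(x$dose)) do.call(dose_regimen, c(list(regimen), x$dose))
  pipeline_config(expression = x$expression, gmt = x$gmt, regimen = regimen,
                  out_dir = x$out_dir %||% tempfile("paldyn_"),
                  alpha_fc = x$alpha_fc %||% 0.05,
                  alpha_fp = x$alpha_fp %||% 0.05,
                  alpha_filter = x$alpha_filter %||% 0.05,
                  n_boot = x$n_boot %||% 1000,
                  k_max = x$k_max %||% 4,
                  min_measured = x$min_measured %||% 3,
                  seed = x$seed %||% 1L,
                  pk = pk, receptor = rp, dose = dz)
}

#' Run the full pathway-pharmacodynamics pipeline
#'
#' Executes filter -> z-score -> coverage -> PAL + significance ->
#' bootstrap ensemble -> clustering -> PK/receptor simulation -> model
#' fitting -> classification, logging each stage with its parameters, and
#' writes per-pathway JSON plus a summary TSV under `config$out_dir`.  A
#' stage failure aborts with the stage name; outputs of completed stages
#' are retained.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress stage logging.
#' @return invisibly, a list with `summary` (data.frame), `results`
#'   (per-pathway details) and `paths` of the written files.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  log_ <- function(...) if (!quiet) message("[paldyn] ", sprintf(...))
  stage <- function(name, expr)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  dataset <- stage("read_expression",
    if (inherits(config$expression, "expression_dataset")) config$expression
    else read_expression_tsv(config$expression))
  pathways <- stage("read_gmt",
    if (is.list(config$gmt) && !is.character(config$gmt)) config$gmt
    else read_gmt(config$gmt))
  log_("inputs: %d genes, %d pathways, regimen=%s, seed=%d",
       nrow(dataset$values), length(pathways), config$regimen, config$seed)

  active <- stage("filter_active_genes",
                  filter_active_genes(dataset, config$alpha_filter))
  log_("active-gene filter (alpha=%.3g): %d of %d genes retained",
       config$alpha_filter, length(active), nrow(dataset$values))
  filtered <- subset_genes(dataset, active)

  universe <- unique(unlist(lapply(pathways, `[[`, "gene_ids")))
  z <- stage("zscore_profiles", zscore_profiles(filtered))

  times <- sort(unique(c(
    seq(0, config$dose$horizon_h, length.out = 601),
    seq(0, min(2, config$dose$horizon_h), length.out = 101))))
  pkrec <- stage("pkpd_simulation", {
    forcing <- pk_forcing(config$pk, config$dose)
    rec <- simulate_receptor(config$receptor, forcing, times)
    rec
  })
  log_("PK/receptor simulated over [0, %g] h (peak DRN = %.3g)",
       config$dose$horizon_h, max(pkrec$DRN))
  drn <- data.frame(time = pkrec$time, DRN = pkrec$DRN)

  analyse_pathway <- function(pw) {
      cs <- coverage_stats(pw, rownames(z), universe)
      if (cs$n_measured_in_pathway < max(2, config$min_measured))
        return(NULL)
      ps <- pal_significance(pw$gene_ids, z, n_boot = config$n_boot,
                             seed = config$seed + 17L)
      gate <- significant_pathways(cs, ps, config$alpha_fc, config$alpha_fp)
      if (!gate$significant) return(NULL)
      ens <- bootstrap_pal_ensemble(pw$gene_ids, filtered,
                                    n_boot = config$n_boot,
                                    seed = config$seed + 31L,
                                    alpha_fp = config$alpha_fp)
      fits <- list(); labels <- character(); clusters <- list()
      if (nrow(ens) >= 2) {
        k <- choose_k_gap(ens, k_max = min(config$k_max, nrow(ens)),
                          seed = config$seed + 43L)
        clusters <- cluster_centroids(ens, k, seed = config$seed + 57L,
                                      pathway_id = pw$pathway_id)
        tpz <- attr(z, "timepoints_h")
        for (cl in clusters) {
          rk <- select_model(cl$centroid, tpz, drn, seed = config$seed + 71L,
                             control = config$fit_control)
          best <- rk[[1]]
          fits[[length(fits) + 1L]] <- best
          labels <- c(labels, classify_fit(best, drn, times, config$regimen))
        }
      }
      list(pathway = pw, coverage = cs, significance = ps, gate = gate,
           clusters = clusters, fits = fits, labels = labels)
  }

  results <- list(); rows <- list()
  for (pw in pathways) {
    res <- stage(paste0("pathway_", pw$pathway_id), analyse_pathway(pw))
    if (is.null(res)) next
    results[[pw$pathway_id]] <- res
    mech <- unique(vapply(res$fits, `[[`, "", "model_type"))
    resp <- paste(unique(c(paste0(mech, "-mediated"), res$labels)),
                  collapse = "/")
    rows[[pw$pathway_id]] <- data.frame(
      pathway = res$pathway$name, pathway_id = pw$pathway_id,
      n_genes = res$coverage$n_pathway_genes,
      n_measured = res$coverage$n_measured_in_pathway,
      f_c = res$coverage$f_c, f_c_pvalue = res$coverage$f_c_pvalue,
      total_fp = res$gate$total_fp,
      n_clusters = length(res$clusters),
      response = resp, stringsAsFactors = FALSE)
    log_("pathway %s: f_c=%s (p=%.3g), total f_p=%s, %d cluster(s), %s",
         pw$pathway_id, percent_half_up(res$coverage$f_c),
         res$coverage$f_c_pvalue, percent_half_up(res$gate$total_fp),
         length(res$clusters), resp)

    jpath <- file.path(config$out_dir, paste0(pw$pathway_id, ".json"))
    jsonlite::write_json(list(
      pathway_id = pw$pathway_id, name = res$pathway$name,
      f_c = res$coverage$f_c, f_c_pvalue = res$coverage$f_c_pvalue,
      f_p = res$significance$f_p, f_p_pvalue = res$significance$f_p_pvalue,
      total_fp = res$gate$total_fp,
      clusters = lapply(res$clusters, function(cl)
        list(centroid = cl$centroid, sd = cl$sd, n = cl$n)),
      fits = lapply(res$fits, function(f)
        list(model_type = f$model_type,
             sign_variant = as.list(f$sign_variant),
             params = as.list(f$params), a = f$a, b = f$b, rss = f$rss)),
      labels = res$labels),
      jpath, auto_unbox = TRUE, digits = NA)
  }

  summary_df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pathway = character(), pathway_id = character(),
               n_genes = integer(), n_measured = integer(), f_c = numeric(),
               f_c_pvalue = numeric(), total_fp = numeric(),
               n_clusters = integer(), response = character())
  rownames(summary_df) <- NULL
  tsv <- file.path(config$out_dir, "summary.tsv")
  write.table(report_table(summary_df), tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  log_("%d significant pathway(s); summary written to %s",
       nrow(summary_df), tsv)
  invisible(list(summary = summary_df, results = results,
                 paths = c(summary = tsv, out_dir = config$out_dir)))
}

#' Format the pipeline summary with integer percents
#'
#' Renders `f_c` and `total_fp` as round-half-up integer percents, the
#' convention of the published coverage tables (0.625 prints as "63%").
#'
#' @param summary_df the `summary` data.frame from [run_pipeline()] (or any
#'   data.frame with `f_c` and `total_fp` fraction columns).
#' @return data.frame with `f_c` and `total_fp` as `"NN%"` strings.
#' @export
report_table <- function(summary_df) {
  out <- summary_df
  if (nrow(out)) {
    out$f_c <- percent_half_up(out$f_c)
    out$total_fp <- percent_half_up(out$total_fp)
  }
  out
}
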