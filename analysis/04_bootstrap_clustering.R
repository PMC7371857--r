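#!/usr/bin/env Rscript
# 04 — Bootstrap PAL ensembles and clustering.
#
# For each significant pathway: resample every gene about its replicate
# mean/SD (N bootstraps), retain the leading significant PALs, select the
# cluster number with the gap statistic and summarize clusters as
# centroid +/- per-timepoint SD.  Writes results/clusters_<regimen>.json.

suppressPackageStartupMessages(library(paldyn))
n_boot <- 200  # desk-scale (study value: 1000)

for (regimen in c("acute", "chronic")) {
  dataset <- read_expression_tsv(file.path("results/data", regimen,
                                           "expression.tsv"))
  pal <- jsonlite::read_json(sprintf("results/pal_%s.json", regimen),
                             simplifyVector = TRUE)
  active <- filter_active_genes(dataset)
  filtered <- subset_genes(dataset, active)
  pathways <- read_gmt(file.path("results/data", regimen, "pathways.gmt"))

  out <- list()
  for (id in names(pal)) {
    if (!isTRUE(pal[[id]]$significant)) next
    ens <- bootstrap_pal_ensemble(pathways[[id]]$gene_ids, filtered,
                                  n_boot = n_boot, seed = 31L)
    if (nrow(ens) < 2) next
    k <- choose_k_gap(ens, k_max = min(4, nrow(ens)), seed = 43L)
    clusters <- cluster_centroids(ens, k, seed = 57L, pathway_id = id)
    cat(sprintf("%s %s: %d retained bootstrap PALs, gap k = %d, sizes %s\n",
                regimen, id, nrow(ens), as.integer(k),
                paste(vapply(clusters, `[[`, 1L, "n"), collapse = "/")))
    out[[id]] <- list(
      pathway_id = id, n_profiles = nrow(ens), k = as.integer(k),
      timepoints_h = attr(ens, "timepoints_h"),
      clusters = lapply(clusters, function(cl)
        list(centroid = cl$centroid, sd = cl$sd, n = cl$n)))
  }
  jsonlite::write_json(out, sprintf("results/clusters_%s.json", regimen),
                       auto_unbox = TRUE, digits = NA)
  cat(sprintf("-> results/clusters_%s.json\n", regimen))
}
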