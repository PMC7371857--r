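# ExpressionDataset: gene x (timepoint x replicate) matrices with time
# annotations, the raw material of PAL extraction.

#' Construct an expression dataset
#'
#' @param values numeric matrix, genes x observations; row names are gene ids
#'   (or supply `gene_ids`).
#' @param timepoints_h numeric vector, the timepoint (hours) of each column.
#' @param replicate_index integer vector, the replicate number of each column.
#' @param gene_ids optional character vector of gene identifiers.
#' @return object of class `expression_dataset`.
#' @export
expression_dataset <- function(values, timepoints_h, replicate_index,
                               gene_ids = rownames(values)) {
  values <- as.matrix(values)
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(values)))
  stopifnot(length(timepoints_h) == ncol(values),
            length(replicate_index) == ncol(values),
            length(gene_ids) == nrow(values))
  if (!all(is.finite(values)))
    paldyn_stop("paldyn_shape_error", "expression values must be finite")
  rownames(values) <- gene_ids
  colnames(values) <- sprintf("t%s_r%d", format(timepoints_h, trim = TRUE,
                                                scientific = FALSE),
                              as.integer(replicate_index))
  structure(list(values = values,
                 gene_ids = gene_ids,
                 timepoints_h = as.numeric(timepoints_h),
                 replicate_index = as.integer(replicate_index)),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> %d genes x %d observations (%d timepoints)\n",
              nrow(x$values), ncol(x$values), length(unique(x$timepoints_h))))
  invisible(x)
}

#' Unique ordered timepoints of a dataset
#' @param dataset an `expression_dataset`.
#' @return numeric vector of unique timepoints, ascending.
#' @export
dataset_timepoints <- function(dataset) sort(unique(dataset$timepoints_h))

#' Subset a dataset to a set of genes
#' @param dataset an `expression_dataset`.
#' @param gene_ids genes to keep (order preserved as in the dataset).
#' @return an `expression_dataset`.
#' @export
subset_genes <- function(dataset, gene_ids) {
  keep <- dataset$gene_ids %in% gene_ids
  expression_dataset(dataset$values[keep, , drop = FALSE],
                     dataset$timepoints_h, dataset$replicate_index,
                     dataset$gene_ids[keep])
}

#' Stack two datasets sharing the same observation columns
#' @param ... `expression_dataset` objects with identical timepoint and
#'   replicate structure.
#' @return an `expression_dataset` holding all genes.
#' @export
bind_genes <- function(...) {
  ds <- list(...)
  ref <- ds[[1]]
  for (d in ds[-1])
    stopifnot(identical(d$timepoints_h, ref$timepoints_h),
              identical(d$replicate_index, ref$replicate_index))
  expression_dataset(do.call(rbind, lapply(ds, `[[`, "values")),
                     ref$timepoints_h, ref$replicate_index,
                     unlist(lapply(ds, `[[`, "gene_ids")))
}

#' Per-gene per-timepoint replicate mean and SD
#'
#' Replicate SD uses the sample (n-1) convention.  Timepoints with a single
#' replicate get `NA` SD here; downstream consumers substitute the gene's
#' pooled SD across timepoints (see [bootstrap_pal_ensemble()]).
#'
#' @param dataset an `expression_dataset`.
#' @return list with `timepoints_h`, matrices `mean` and `sd`
#'   (genes x timepoints) and `n_rep` (replicates per timepoint).
#' @export
replicate_stats <- function(dataset) {
  tp <- dataset_timepoints(dataset)
  grp <- match(dataset$timepoints_h, tp)
  n <- tabulate(grp, nbins = length(tp))
  v <- dataset$values
  sums <- t(rowsum(t(v), grp))              # genes x timepoints
  m <- sweep(sums, 2, n, "/")
  sq <- t(rowsum(t(v^2), grp))
  ss <- sq - sweep(m^2, 2, n, "*")
  s <- sqrt(sweep(pmax(ss, 0), 2, pmax(n - 1, 1), "/"))
  s[, n < 2] <- NA_real_
  dimnames(m) <- dimnames(s) <- list(dataset$gene_ids, paste0("t", tp))
  list(timepoints_h = tp, mean = m, sd = s, n_rep = n)
}

#' Write / read an expression dataset as TSV
#'
#' First column `gene_id`; remaining columns labelled `t<hours>_r<replicate>`.
#'
#' @param dataset an `expression_dataset`.
#' @param path file path.
#' @return `write_expression_tsv`: the path, invisibly.
#'   `read_expression_tsv`: an `expression_dataset`.
#' @export
write_expression_tsv <- function(dataset, path) {
  df <- data.frame(gene_id = dataset$gene_ids,
                   dataset$values, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) paldyn_stop("paldyn_io_error", "no such file: ", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "gene_id")
    paldyn_stop("paldyn_io_error", "first column must be gene_id: ", path)
  lab <- names(df)[-1]
  m <- regmatches(lab, regexec("^t([0-9.eE+-]+)_r([0-9]+)$", lab))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad))
    paldyn_stop("paldyn_io_error", "malformed column label(s): ",
                paste(lab[bad], collapse = ", "))
  tp <- vapply(m, function(z) as.numeric(z[2]), 1.0)
  rep_i <- vapply(m, function(z) as.integer(z[3]), 1L)
  expression_dataset(as.matrix(df[, -1, drop = FALSE]), tp, rep_i,
                     as.character(df$gene_id))
}
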