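# Pathway catalogs: GMT gene sets, fractional coverage f_c and its
# one-tailed Fisher exact (hypergeometric) p-value against the catalog-wide
# gene universe.

#' Construct a pathway definition
#' @param pathway_id identifier, e.g. `"rno03050"`.
#' @param name human-readable pathway name.
#' @param gene_ids member gene identifiers (deduplicated, non-empty).
#' @param subgroup optional functional subgroup label.
#' @return object of class `pathway_definition`.
#' @export
pathway_definition <- function(pathway_id, name, gene_ids, subgroup = NULL) {
  gene_ids <- unique(as.character(gene_ids))
  if (length(gene_ids) == 0)
    paldyn_stop("paldyn_parse_error", "pathway ", pathway_id, " has no genes")
  structure(list(pathway_id = as.character(pathway_id), name = as.character(name),
                 gene_ids = gene_ids, subgroup = subgroup),
            class = "pathway_definition")
}

#' Read / write pathway gene sets in GMT format
#'
#' Standard tab-separated GMT: `set_id<TAB>description<TAB>gene1<TAB>gene2...`.
#' Blank lines are ignored; duplicate genes within a line are counted once;
#' lines with fewer than three fields raise a parse error naming the line.
#'
#' @param path GMT file path.
#' @return `read_gmt`: named list of [pathway_definition()] objects.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) paldyn_stop("paldyn_io_error", "no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  defs <- lapply(which(keep), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    f <- f[nzchar(f)]
    if (length(f) < 3)
      paldyn_stop("paldyn_parse_error", "GMT line ", i,
                  ": expected at least 3 tab-separated fields")
    pathway_definition(f[1], f[2], f[-(1:2)])
  })
  names(defs) <- vapply(defs, `[[`, "", "pathway_id")
  defs
}

#' @rdname read_gmt
#' @param pathways list of `pathway_definition` objects.
#' @export
write_gmt <- function(pathways, path) {
  lines <- vapply(pathways, function(p)
    paste(c(p$pathway_id, p$name, p$gene_ids), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Fractional coverage of a pathway
#'
#' The fraction of a pathway's genes for which measured profiles are
#' available: `f_c = |pathway ∩ measured| / |pathway|`.
#'
#' @param pathway a [pathway_definition()].
#' @param measured_gene_ids gene identifiers present in the dataset.
#' @return object of class `coverage_stats` with `n_pathway_genes`,
#'   `n_measured_in_pathway`, `f_c` (and `f_c_pvalue = NA`; see
#'   [coverage_pvalue()]).
#' @export
#' @examples
#' p <- pathway_definition("pw1", "toy", paste0("g", 1:48))
#' fractional_coverage(p, paste0("g", 1:14))$f_c  # 14/48
fractional_coverage <- function(pathway, measured_gene_ids) {
  stopifnot(inherits(pathway, "pathway_definition"))
  k <- length(intersect(pathway$gene_ids, unique(as.character(measured_gene_ids))))
  structure(list(pathway_id = pathway$pathway_id,
                 n_pathway_genes = length(pathway$gene_ids),
                 n_measured_in_pathway = k,
                 f_c = k / length(pathway$gene_ids),
                 f_c_pvalue = NA_real_),
            class = "coverage_stats")
}

#' Upper-tail Fisher exact p-value of pathway coverage
#'
#' Probability of observing at least the seen overlap between the pathway
#' and the measured gene set, hypergeometrically, with the universe taken as
#' the set of unique genes across all catalog pathways.  Measured genes are
#' intersected with the universe before the 2x2 table is formed.
#'
#' @param pathway a [pathway_definition()]; must be a subset of `universe_gene_ids`.
#' @param measured_gene_ids measured gene identifiers.
#' @param universe_gene_ids the background gene universe.
#' @return a probability in `[0, 1]`.
#' @export
coverage_pvalue <- function(pathway, measured_gene_ids, universe_gene_ids) {
  stopifnot(inherits(pathway, "pathway_definition"))
  U <- unique(as.character(universe_gene_ids))
  if (!all(pathway$gene_ids %in% U))
    paldyn_stop("paldyn_consistency_error",
                "pathway ", pathway$pathway_id, " is not a subset of the universe")
  M <- intersect(unique(as.character(measured_gene_ids)), U)
  k <- length(intersect(pathway$gene_ids, M))
  phyper(k - 1, length(pathway$gene_ids),
         length(U) - length(pathway$gene_ids), length(M),
         lower.tail = FALSE)
}

#' Coverage statistics with p-value
#'
#' Convenience wrapper combining [fractional_coverage()] and
#' [coverage_pvalue()].
#'
#' @inheritParams coverage_pvalue
#' @return a `coverage_stats` object with `f_c_pvalue` filled in.
#' @export
coverage_stats <- function(pathway, measured_gene_ids, universe_gene_ids) {
  cs <- fractional_coverage(pathway, measured_gene_ids)
  cs$f_c_pvalue <- coverage_pvalue(pathway, measured_gene_ids, universe_gene_ids)
  cs
}
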