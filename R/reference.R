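# Shipped reference table: the published coverage summary of the 29
# pathways significant under both acute (GSE490) and chronic (GSE5101) MPL
# administration in rat gastrocnemius muscle — KEGG pathway sizes, unique
# measured genes, integer-percent fractional coverage (f_c) and total
# fraction of pathway activity (total f_p), and the reported response class.

#' Published MPL muscle pathway coverage summary
#'
#' Loads the reference table of the 29 pathways significant under both
#' acute and chronic MPL dosing in rat muscle, with KEGG pathway gene
#' counts, unique measured genes per dataset, printed integer-percent
#' fractional coverage and total fraction of pathway activity, and the
#' reported response classes.  Used to check the coverage arithmetic
#' (`unique / n_genes` re-rounded must reproduce every printed percent).
#'
#' @return data.frame with one row per pathway.
#' @export
mpl_muscle_pathways <- function() {
  path <- system.file("extdata", "mpl_muscle_pathways.tsv", package = "paldyn",
                      mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE, check.names = TRUE)
}
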