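#' Tidy a pipeline result into its paracluster table
#'
#' @param x a `paraclust_result`.
#' @param ... unused.
#' @return the merged `paracluster_table` tibble.
#' @export
tidy.paraclust_result <- function(x, ...) {
  x$paraclusters
}

#' One-row summary of a pipeline result
#'
#' @param x a `paraclust_result`.
#' @param ... unused.
#' @return one-row tibble: genome size, dataset count, candidate and
#'   significant chain counts, merged paracluster count, genes and percent
#'   of the genome in paraclusters.
#' @export
glance.paraclust_result <- function(x, ...) {
  merged <- x$metrics$summary[x$metrics$summary$dataset == "merged", ]
  tibble(
    n_genes = nrow(x$index),
    n_datasets = length(unique(x$annotations$dataset)),
    n_chains = nrow(x$chains),
    n_significant = nrow(x$significant),
    e_threshold = x$config$e_threshold,
    paracluster_count = nrow(x$paraclusters),
    genes_in_paraclusters = if (nrow(merged) == 1) merged$genes_in_paraclusters else 0L,
    percent_genes = if (nrow(merged) == 1) merged$percent_genes else 0
  )
}
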