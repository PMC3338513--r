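#' Genome-wide paraclustering summary
#'
#' Computes, per dataset and for the merged paracluster set, the paracluster
#' count, number of genes in paraclusters and the percentage of the genome
#' those genes represent; the paracluster-size distribution (size measured
#' as `l`, the number of paralog members, not the span) with gene counts
#' including and excluding interstitial genes and the cumulative percentage
#' of the genome; and adjacency fractions: the percentage of all genes with
#' a co-cluster paralog directly adjacent (rank distance 1) or within 10
#' ranks.
#'
#' @param paraclusters a `paracluster_table` from [merge_paraclusters()].
#' @param chains the significant chain table the paraclusters were merged
#'   from (provides the per-dataset rows).
#' @param index the `genome_index`.
#' @return a `genome_summary` list with tibbles `summary`,
#'   `size_distribution` and `adjacency`.
#' @export
genome_metrics <- function(paraclusters, chains, index) {
  genome_n <- nrow(index)
  datasets <- sort(unique(chains$dataset))

  per_ds <- purrr::map_dfr(datasets, function(ds) {
    sub <- chains[chains$dataset == ds, ]
    genes <- unique(unlist(sub$member_genes, use.names = FALSE))
    tibble(
      dataset = ds,
      paracluster_count = nrow(sub),
      genes_in_paraclusters = length(genes),
      percent_genes = length(genes) / genome_n * 100
    )
  })
  merged_genes <- unique(unlist(paraclusters$member_gene_ids, use.names = FALSE))
  summary <- bind_rows(per_ds, tibble(
    dataset = "merged",
    paracluster_count = nrow(paraclusters),
    genes_in_paraclusters = length(merged_genes),
    percent_genes = length(merged_genes) / genome_n * 100
  ))

  size_distribution <- paraclusters |>
    mutate(size = .data$n_members) |>
    group_by(.data$size) |>
    summarise(
      n_clusters = n(),
      genes_excl_interstitial = sum(.data$n_members),
      genes_incl_interstitial = sum(.data$n_members + .data$n_interstitial),
      .groups = "drop"
    ) |>
    arrange(.data$size) |>
    mutate(
      cumulative_percent_genes =
        cumsum(.data$genes_excl_interstitial) / genome_n * 100
    )

  adjacency <- tibble(
    metric = c("adjacent", "within_10"),
    n_genes = c(
      adjacency_count(paraclusters, 1L),
      adjacency_count(paraclusters, 10L)
    )
  ) |>
    mutate(percent = .data$n_genes / genome_n * 100)

  structure(
    list(summary = summary, size_distribution = size_distribution,
         adjacency = adjacency, n_genes = genome_n),
    class = "genome_summary"
  )
}

# number of paracluster member genes whose nearest co-cluster member is
# within `within` ranks
adjacency_count <- function(paraclusters, within) {
  if (nrow(paraclusters) == 0) return(0L)
  sum(map_int(paraclusters$member_ranks, function(r) {
    if (length(r) < 2) return(0L)
    d <- diff(r)
    sum(c(d[1], pmin(d[-length(d)], d[-1]), d[length(d)]) <= within)
  }))
}

#' @export
print.genome_summary <- function(x, ...) {
  cat("Genome paraclustering summary (N =", x$n_genes, "genes)\n")
  print(x$summary)
  cat("\nAdjacency of co-cluster paralogs:\n")
  print(x$adjacency)
  invisible(x)
}

#' Per-family clustering fractions
#'
#' For every annotation term (gene family) of a dataset: the family size
#' `m`, the number of members inside any paracluster, and the clustered
#' fraction. Large, recently expanded families tend to be far more
#' clustered than small ones; [family_size_effect()] bins these fractions
#' for families above a size cutoff.
#'
#' @param annotations annotation tibble.
#' @param paraclusters a `paracluster_table`.
#' @param dataset optional dataset name to restrict to.
#' @return tibble `dataset`, `term_id`, `size`, `members_in_clusters`,
#'   `fraction`.
#' @export
family_clustering_fractions <- function(annotations, paraclusters, dataset = NULL) {
  ann <- annotations
  if (!is.null(dataset)) ann <- ann[ann$dataset %in% dataset, ]
  clustered <- unique(unlist(paraclusters$member_gene_ids, use.names = FALSE))
  ann |>
    distinct(.data$dataset, .data$gene_id, .data$term_id) |>
    group_by(.data$dataset, .data$term_id) |>
    summarise(
      size = n(),
      members_in_clusters = sum(.data$gene_id %in% clustered),
      .groups = "drop"
    ) |>
    mutate(fraction = .data$members_in_clusters / .data$size) |>
    arrange(.data$dataset, desc(.data$size))
}

#' Family-size effect histogram
#'
#' Counts families at or above a size cutoff grouped by the fraction of
#' their members contained within paraclusters.
#'
#' @param fractions output of [family_clustering_fractions()].
#' @param min_size family-size cutoff (default 10).
#' @param breaks fraction bin boundaries (default fifths of `[0, 1]`).
#' @return tibble `dataset`, `fraction_bin`, `n_families`.
#' @export
family_size_effect <- function(fractions, min_size = 10,
                               breaks = seq(0, 1, by = 0.2)) {
  fractions |>
    filter(.data$size >= min_size) |>
    mutate(fraction_bin = cut(.data$fraction, breaks = breaks,
                              include.lowest = TRUE)) |>
    count(.data$dataset, .data$fraction_bin, name = "n_families", .drop = FALSE)
}

#' Cross-species paracluster sharing
#'
#' A paracluster of species A is *shared* with species B if at least one of
#' its member genes has a relation partner (by default an in-paralog, i.e. a
#' duplicate that arose after the two species diverged) lying inside any
#' paracluster of B; clusters shared with none of the compared species are
#' species specific.
#'
#' @param clusters_a,clusters_b `paracluster_table`s of the two species.
#' @param ortholog_map tibble `gene_a`, `gene_b`, `relation` with relations
#'   among `"inparalog"`, `"ortholog"`, `"outparalog"`.
#' @param relation relation value(s) that assert sharing (default
#'   `"inparalog"`).
#' @return one-row tibble: `n_clusters`, `n_shared`, `fraction_shared`,
#'   `fraction_specific`.
#' @export
cluster_sharing <- function(clusters_a, clusters_b, ortholog_map,
                            relation = "inparalog") {
  bad <- setdiff(unique(ortholog_map$relation),
                 c("inparalog", "ortholog", "outparalog"))
  if (length(bad) > 0) {
    abort(paste0("unknown relation value(s): ", paste(bad, collapse = ", ")))
  }
  map_use <- ortholog_map[ortholog_map$relation %in% relation, , drop = FALSE]
  b_genes <- unique(unlist(clusters_b$member_gene_ids, use.names = FALSE))
  partners <- split(map_use$gene_b, map_use$gene_a)
  shared <- map_lgl(clusters_a$member_gene_ids, function(members) {
    p <- unlist(partners[members], use.names = FALSE)
    length(p) > 0 && any(p %in% b_genes)
  })
  tibble(
    n_clusters = nrow(clusters_a),
    n_shared = sum(shared),
    fraction_shared = if (nrow(clusters_a) == 0) NA_real_ else mean(shared),
    fraction_specific = if (nrow(clusters_a) == 0) NA_real_ else mean(!shared)
  )
}

#' Sweep the expectation threshold
#'
#' Re-filters scored chains at each threshold and reports, per dataset and
#' merged, the paracluster count and number of clustered genes. Because the
#' significant sets are nested across thresholds, totals are non-decreasing.
#'
#' @param scored_chains a scored chain table (all candidate chains).
#' @param index the `genome_index`.
#' @param thresholds ascending expectation thresholds.
#' @return tibble `threshold`, `dataset`, `paracluster_count`,
#'   `genes_in_paraclusters`, `percent_genes`.
#' @export
threshold_sweep <- function(scored_chains, index,
                            thresholds = c(0.01, 0.05, 0.1, 0.15)) {
  stopifnot(!is.unsorted(thresholds))
  purrr::map_dfr(thresholds, function(t) {
    sig <- filter_significant(scored_chains, t)
    pc <- merge_paraclusters(sig, index)
    genome_metrics(pc, sig, index)$summary |>
      mutate(threshold = t) |>
      select("threshold", everything())
  })
}

#' Sweep the maximum gap length
#'
#' Re-runs chain detection, scoring and merging for each allowed gap length
#' and reports total clustered genes. The effect of the gap parameter is
#' concentrated at small values and diminishes as it grows.
#'
#' @param index the `genome_index`.
#' @param annotations annotation tibble.
#' @param gaps gap lengths to test (default `0:15`).
#' @param threshold expectation threshold (default 0.01).
#' @param collapse_nested passed to [chaining_config()].
#' @return tibble `max_gap`, `dataset`, `paracluster_count`,
#'   `genes_in_paraclusters`, `percent_genes`.
#' @export
gap_sweep <- function(index, annotations, gaps = 0:15, threshold = 0.01,
                      collapse_nested = TRUE) {
  purrr::map_dfr(gaps, function(g) {
    cfg <- chaining_config(max_gap = g, collapse_nested = collapse_nested)
    sig <- detect_chains(index, annotations, cfg) |>
      score_chains(annotations, index) |>
      filter_significant(threshold)
    pc <- merge_paraclusters(sig, index)
    genome_metrics(pc, sig, index)$summary |>
      mutate(max_gap = g) |>
      select("max_gap", everything())
  })
}
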