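#' Merge significant chains across datasets into paraclusters
#'
#' Two chains (from the same or different datasets) belong to the same
#' paracluster if and only if their member-gene sets intersect; the relation
#' is closed transitively. Membership intersection, not genomic-interval
#' overlap, is the criterion, so adjacent or nested clusters of unrelated
#' families stay separate. Members of a paracluster are the union of the
#' contributing chains' members; interstitial genes are recomputed from the
#' merged span, and a gene that is interstitial for one dataset but a member
#' in another counts as a member.
#'
#' @param chains a scored, significance-filtered chain table.
#' @param index the `genome_index`.
#' @return a `paracluster_table` tibble: `cluster_id`, `chromosome`,
#'   `start_rank`, `end_rank`, `n_members`, `n_interstitial`, list-columns
#'   `member_ranks`, `member_gene_ids`, `interstitial_gene_ids`,
#'   `datasets`, `chain_ids`.
#' @export
merge_paraclusters <- function(chains, index) {
  if (nrow(chains) == 0) {
    out <- tibble(
      cluster_id = character(), chromosome = character(),
      start_rank = integer(), end_rank = integer(),
      n_members = integer(), n_interstitial = integer(),
      member_ranks = list(), member_gene_ids = list(),
      interstitial_gene_ids = list(), datasets = list(), chain_ids = list()
    )
    class(out) <- c("paracluster_table", class(out))
    return(out)
  }
  n_chain <- nrow(chains)
  ranks <- unlist(chains$members, use.names = FALSE)
  owner <- rep(seq_len(n_chain), lengths(chains$members))
  # connect chains sharing a member gene
  by_rank <- split(owner, ranks)
  edges <- purrr::map_dfr(by_rank[lengths(by_rank) > 1], function(ch) {
    ch <- sort(unique(ch))
    if (length(ch) < 2) return(NULL)
    tibble(from = ch[1], to = ch[-1])
  })
  g <- igraph::make_empty_graph(n = n_chain, directed = FALSE)
  if (nrow(edges) > 0) {
    g <- igraph::add_edges(g, rbind(edges$from, edges$to))
  }
  comp <- igraph::components(g)$membership

  out <- tibble(comp = comp, i = seq_len(n_chain)) |>
    group_by(.data$comp) |>
    group_modify(function(d, key) {
      idx <- d$i
      mr <- sort(unique(unlist(chains$members[idx], use.names = FALSE)))
      span <- seq(min(mr), max(mr))
      inter <- setdiff(span, mr)
      tibble(
        chromosome = chains$chromosome[idx[1]],
        start_rank = min(mr),
        end_rank = max(mr),
        n_members = length(mr),
        n_interstitial = length(inter),
        member_ranks = list(mr),
        member_gene_ids = list(index$gene_id[mr]),
        interstitial_gene_ids = list(index$gene_id[inter]),
        datasets = list(sort(unique(chains$dataset[idx]))),
        chain_ids = list(sort(chains$chain_id[idx]))
      )
    }) |>
    ungroup() |>
    select(-"comp") |>
    arrange(.data$start_rank) |>
    mutate(cluster_id = sprintf("pc%04d", row_number())) |>
    select("cluster_id", everything())
  class(out) <- c("paracluster_table", class(out))
  out
}

#' Gene overlap between datasets' significant chains
#'
#' Cell (i, j) is the number of genes found in significant chains of dataset
#' i that are also in significant chains of dataset j; the diagonal gives
#' each dataset's clustered-gene total. The matrix is symmetric with a
#' maximal diagonal.
#'
#' @param chains a scored, significance-filtered chain table.
#' @return a symmetric integer matrix with dataset dimnames.
#' @export
dataset_overlap_matrix <- function(chains) {
  datasets <- sort(unique(chains$dataset))
  gene_sets <- lapply(setNames(datasets, datasets), function(ds) {
    unique(unlist(chains$member_genes[chains$dataset == ds], use.names = FALSE))
  })
  n <- length(datasets)
  m <- matrix(0L, n, n, dimnames = list(datasets, datasets))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      m[i, j] <- length(intersect(gene_sets[[i]], gene_sets[[j]]))
    }
  }
  m
}
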