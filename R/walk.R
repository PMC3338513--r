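# Related forward pairs within max_span, per dataset: one row per unordered
# pair of ranks on the same chromosome sharing >= 1 term, rank2 > rank1.
related_pairs <- function(index, annotations, max_span) {
  ann <- annotations |>
    distinct(.data$dataset, .data$gene_id, .data$term_id)
  unknown <- setdiff(unique(ann$gene_id), index$gene_id)
  if (length(unknown) > 0) {
    abort(paste0(
      "annotated gene(s) absent from the genome index: ",
      paste(head(unknown, 10), collapse = ", ")
    ))
  }
  ann <- ann |>
    inner_join(
      select(as_tibble(index), "gene_id", "chromosome", "rank"),
      by = "gene_id"
    )
  ann |>
    inner_join(ann,
      by = c("dataset", "term_id", "chromosome"),
      suffix = c("_1", "_2"), relationship = "many-to-many"
    ) |>
    filter(.data$rank_2 > .data$rank_1,
           .data$rank_2 - .data$rank_1 <= max_span - 1) |>
    distinct(.data$dataset, .data$chromosome, .data$rank_1, .data$rank_2)
}

#' Chromosome-walk relatedness profile
#'
#' Walks each chromosome taking every gene in turn and asking whether the
#' gene `n` positions further along (in rank order, forward direction)
#' shares at least one annotation term; `n = 2` means the two genes are
#' adjacent. Each forward pair is counted once per dataset, pairs never
#' straddle chromosome boundaries, and all spans up to `max_span` are
#' tabulated.
#'
#' @param index a `genome_index`.
#' @param annotations annotation tibble (`dataset`, `gene_id`, `term_id`).
#' @param max_span largest span tabulated (default 100).
#' @return a `walk_profile` tibble: `dataset`, `span` (2..`max_span`),
#'   `count`.
#' @export
relatedness_profile <- function(index, annotations, max_span = 100) {
  stopifnot(max_span >= 2)
  validate_genome_index(index)
  datasets <- sort(unique(annotations$dataset))
  pairs <- related_pairs(index, annotations, max_span)
  prof <- pairs |>
    mutate(span = .data$rank_2 - .data$rank_1 + 1L) |>
    count(.data$dataset, .data$span, name = "count") |>
    tidyr::complete(
      dataset = datasets, span = 2:max_span,
      fill = list(count = 0L)
    ) |>
    arrange(.data$dataset, .data$span)
  attr(prof, "max_span") <- max_span
  attr(prof, "n_genes_evaluated") <- nrow(index)
  class(prof) <- c("walk_profile", class(prof))
  prof
}

#' Distance to the nearest structurally related gene
#'
#' For every gene, the minimum rank distance (1 = adjacent; searched in both
#' directions within the chromosome, capped at `max_span - 1`) to a gene
#' sharing at least one annotation term in the same dataset. Genes with no
#' related gene within the cap fall in an overflow bin (`distance = Inf`).
#'
#' @inheritParams relatedness_profile
#' @return tibble `dataset`, `distance`, `n_genes`; the `Inf` row is the
#'   overflow bin. Counts sum to the genome size for every dataset.
#' @export
nearest_related_histogram <- function(index, annotations, max_span = 100) {
  stopifnot(max_span >= 2)
  datasets <- sort(unique(annotations$dataset))
  pairs <- related_pairs(index, annotations, max_span)
  per_gene <- bind_rows(
    pairs |> transmute(.data$dataset, rank = .data$rank_1,
                       d = .data$rank_2 - .data$rank_1),
    pairs |> transmute(.data$dataset, rank = .data$rank_2,
                       d = .data$rank_2 - .data$rank_1)
  ) |>
    group_by(.data$dataset, .data$rank) |>
    summarise(distance = min(.data$d), .groups = "drop")
  hist <- per_gene |>
    count(.data$dataset, .data$distance, name = "n_genes")
  overflow <- per_gene |>
    count(.data$dataset, name = "n_found") |>
    tidyr::complete(dataset = datasets, fill = list(n_found = 0L)) |>
    mutate(distance = Inf, n_genes = nrow(index) - .data$n_found) |>
    select("dataset", "distance", "n_genes")
  out <- bind_rows(hist, overflow) |>
    arrange(.data$dataset, .data$distance)
  attr(out, "max_span") <- max_span
  out
}

#' Randomly permute gene order
#'
#' Reassigns genes at random to the genome's positional slots, leaving the
#' slot structure (chromosome sizes and rank layout) fixed and every gene's
#' annotations undisturbed; annotation tables keyed by gene id need no
#' change. This is the null model for all proximity statistics.
#'
#' @param index a `genome_index`.
#' @param seed integer seed; the same seed reproduces the same permutation.
#' @return a permuted `genome_index`.
#' @export
permute_gene_order <- function(index, seed) {
  perm <- withr::with_seed(seed, sample.int(nrow(index)))
  out <- index
  out$gene_id <- index$gene_id[perm]
  out$strand <- index$strand[perm]
  out
}

#' Permuted-genome baseline for the relatedness profile
#'
#' Averages the chromosome-walk profile over several randomly permuted
#' genomes, producing the smooth near-flat baseline against which the
#' observed profile is compared. The slight negative slope of the baseline
#' reflects the limiting size of individual chromosomes.
#'
#' @inheritParams relatedness_profile
#' @param n_permutations number of permuted genomes averaged (default 10).
#' @param seed integer seed controlling all permutations.
#' @return a `walk_baseline` tibble: `dataset`, `span`, `mean_count`.
#' @export
permutation_baseline <- function(index, annotations, n_permutations = 10,
                                 max_span = 100, seed = 1) {
  stopifnot(n_permutations >= 1)
  sub_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n_permutations))
  profs <- map(sub_seeds, function(s) {
    relatedness_profile(permute_gene_order(index, s), annotations, max_span)
  })
  base <- bind_rows(profs) |>
    group_by(.data$dataset, .data$span) |>
    summarise(mean_count = mean(.data$count), .groups = "drop") |>
    arrange(.data$dataset, .data$span)
  attr(base, "n_permutations") <- n_permutations
  attr(base, "seed") <- seed
  attr(base, "max_span") <- max_span
  class(base) <- c("walk_baseline", class(base))
  base
}
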