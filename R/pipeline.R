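#' Pipeline run configuration
#'
#' Bundles inputs and parameters for [run_pipeline()]. Inputs may be data
#' frames or file paths (TSV; gene tables may also be BED/GFF3). Defaults
#' are the method's standard operating point: spans up to 100, gap length
#' 15, unlimited gaps, expectation threshold 0.01, ten permutations for the
#' baseline.
#'
#' @param genes gene table (data frame or path).
#' @param annotations term-based annotation table (data frame or path).
#' @param pairs optional pairwise paralogy table (data frame or path);
#'   converted to family terms with [pairs_to_families()].
#' @param out_dir optional output directory; when given, all report files
#'   are written there.
#' @param chromosome_order optional explicit chromosome order.
#' @param dataset_roster optional character vector restricting which
#'   datasets are analysed.
#' @param max_span largest span for the chromosome walk.
#' @param max_gap,max_gaps,collapse_nested chaining parameters, see
#'   [chaining_config()].
#' @param e_threshold expectation threshold for significance.
#' @param n_permutations permuted genomes averaged for the walk baseline.
#' @param do_walk run the chromosome walk and permutation baseline
#'   (the slowest stage; disable for cluster detection only).
#' @param seed integer seed for the permutation baseline.
#' @param verbose log stage boundaries and counts.
#' @return a `run_config` list.
#' @export
run_config <- function(genes, annotations = NULL, pairs = NULL,
                       out_dir = NULL, chromosome_order = NULL,
                       dataset_roster = NULL,
                       max_span = 100, max_gap = 15, max_gaps = Inf,
                       collapse_nested = TRUE, e_threshold = 0.01,
                       n_permutations = 10, do_walk = TRUE, seed = 1,
                       verbose = FALSE) {
  structure(
    list(
      genes = genes, annotations = annotations, pairs = pairs,
      out_dir = out_dir, chromosome_order = chromosome_order,
      dataset_roster = dataset_roster,
      max_span = as.integer(max_span),
      max_gap = as.integer(max_gap),
      max_gaps = max_gaps,
      collapse_nested = isTRUE(collapse_nested),
      e_threshold = e_threshold,
      n_permutations = as.integer(n_permutations),
      do_walk = isTRUE(do_walk),
      seed = as.integer(seed),
      verbose = isTRUE(verbose)
    ),
    class = "run_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; `genes`, `annotations` and
#' `pairs` are file paths resolved relative to the YAML file's directory.
#'
#' @param path YAML file path.
#' @return a `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  y <- yaml::read_yaml(path)
  base <- dirname(path)
  for (key in c("genes", "annotations", "pairs")) {
    if (!is.null(y[[key]]) && !file.exists(y[[key]])) {
      y[[key]] <- file.path(base, y[[key]])
    }
  }
  do.call(run_config, y)
}

load_input <- function(x, reader, what) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1) {
    if (!file.exists(x)) abort(paste0(what, " file not found: ", x))
    return(reader(x))
  }
  as_tibble(x)
}

#' Run the full paracluster-detection pipeline
#'
#' Index construction, optional chromosome walk with permuted-genome
#' baseline, per-dataset chain detection, hypergeometric scoring,
#' expectation filtering, cross-dataset merging, genome metrics, dataset
#' overlap matrix and annotation-coverage audit. When `config$out_dir` is
#' set, all reports are written as TSV/JSON plus a provenance header; two
#' runs with identical configuration and seed produce identical files.
#'
#' @param config a [run_config()].
#' @return a `paraclust_result` list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (config$verbose) message(sprintf(...))

  genes <- load_input(config$genes, read_gene_table, "gene table")
  ann <- load_input(config$annotations, read_annotation_table, "annotation table")
  pairs <- load_input(config$pairs, read_paralog_pairs, "paralog pair table")
  if (is.null(genes)) abort("a gene table is required")
  if (is.null(ann) && is.null(pairs)) {
    abort("at least one of annotations / pairs is required")
  }

  index <- build_gene_index(genes, config$chromosome_order)
  say("indexed %d genes on %d chromosomes", nrow(index),
      nrow(chromosome_spans(index)))

  all_ann <- bind_rows(
    if (!is.null(ann)) ann else NULL,
    if (!is.null(pairs) && nrow(pairs) > 0) pairs_to_families(pairs, index) else NULL
  )
  if (!is.null(config$dataset_roster)) {
    missing_ds <- setdiff(config$dataset_roster, unique(all_ann$dataset))
    if (length(missing_ds) > 0) {
      abort(paste0("dataset(s) not present in the inputs: ",
                   paste(missing_ds, collapse = ", ")))
    }
    all_ann <- all_ann[all_ann$dataset %in% config$dataset_roster, ]
  }
  unknown <- setdiff(unique(all_ann$gene_id), index$gene_id)
  if (length(unknown) > 0) {
    abort(paste0(
      "annotated gene(s) absent from the gene table: ",
      paste(head(unknown, 20), collapse = ", "),
      if (length(unknown) > 20) sprintf(" (and %d more)", length(unknown) - 20) else ""
    ))
  }
  say("annotation datasets: %s", paste(sort(unique(all_ann$dataset)), collapse = ", "))

  walk <- NULL
  if (config$do_walk) {
    profile <- relatedness_profile(index, all_ann, config$max_span)
    baseline <- permutation_baseline(index, all_ann,
      n_permutations = config$n_permutations,
      max_span = config$max_span, seed = config$seed
    )
    nearest <- nearest_related_histogram(index, all_ann, config$max_span)
    walk <- list(profile = profile, baseline = baseline, nearest = nearest)
    say("walk done (max span %d, %d permutations)",
        config$max_span, config$n_permutations)
  }

  cfg <- chaining_config(
    max_gap = config$max_gap, max_gaps = config$max_gaps,
    collapse_nested = config$collapse_nested
  )
  chains <- detect_chains(index, all_ann, cfg) |>
    score_chains(all_ann, index)
  significant <- filter_significant(chains, config$e_threshold)
  say("chains: %d candidates, %d significant at e < %g",
      nrow(chains), nrow(significant), config$e_threshold)

  paraclusters <- merge_paraclusters(significant, index)
  metrics <- genome_metrics(paraclusters, significant, index)
  overlap <- dataset_overlap_matrix(significant)
  audit <- coverage_audit(index, all_ann)
  say("merged into %d paraclusters holding %d genes",
      nrow(paraclusters),
      metrics$summary$genes_in_paraclusters[metrics$summary$dataset == "merged"])

  result <- structure(
    list(
      index = index, annotations = all_ann, walk = walk,
      chains = chains, significant = significant,
      paraclusters = paraclusters, metrics = metrics,
      overlap = overlap, audit = audit, config = config
    ),
    class = "paraclust_result"
  )
  if (!is.null(config$out_dir)) write_reports(result, config$out_dir)
  result
}

#' Annotation-coverage audit
#'
#' Reports, per dataset, the fraction of genes with at least one
#' annotation; per-chromosome coverage; and the genes annotated in no
#' dataset at all ("dark" loci, which still occupy ranks and can only
#' appear as interstitial genes).
#'
#' @param index a `genome_index`.
#' @param annotations annotation tibble.
#' @return a `coverage_audit` list with tibbles `per_dataset`,
#'   `per_chromosome` and character vector `unannotated_genes`.
#' @export
coverage_audit <- function(index, annotations) {
  n <- nrow(index)
  datasets <- sort(unique(annotations$dataset))
  ann <- distinct(annotations, .data$dataset, .data$gene_id)
  per_dataset <- ann |>
    count(.data$dataset, name = "n_annotated") |>
    tidyr::complete(dataset = datasets, fill = list(n_annotated = 0L)) |>
    mutate(coverage = .data$n_annotated / n)
  covered <- unique(ann$gene_id)
  per_chromosome <- as_tibble(index) |>
    mutate(annotated = .data$gene_id %in% covered) |>
    group_by(.data$chromosome) |>
    summarise(
      n_genes = n(), n_annotated = sum(.data$annotated),
      coverage = mean(.data$annotated), .groups = "drop"
    )
  structure(
    list(
      per_dataset = per_dataset,
      per_chromosome = per_chromosome,
      unannotated_genes = sort(setdiff(index$gene_id, covered))
    ),
    class = "coverage_audit"
  )
}

# ---- report writing ------------------------------------------------------

flatten_chain_table <- function(chains) {
  chains |>
    mutate(
      members = map_chr(.data$members, paste, collapse = ","),
      member_genes = map_chr(.data$member_genes, paste, collapse = ","),
      common_terms = map_chr(.data$common_terms, paste, collapse = ","),
      gap_start = map_chr(.data$gap_start, paste, collapse = ","),
      gap_raw = map_chr(.data$gap_raw, paste, collapse = ","),
      gap_eff = map_chr(.data$gap_eff, paste, collapse = ",")
    )
}

flatten_paracluster_table <- function(pc) {
  pc |>
    mutate(
      member_ranks = map_chr(.data$member_ranks, paste, collapse = ","),
      member_gene_ids = map_chr(.data$member_gene_ids, paste, collapse = ","),
      interstitial_gene_ids = map_chr(.data$interstitial_gene_ids, paste, collapse = ","),
      datasets = map_chr(.data$datasets, paste, collapse = ","),
      chain_ids = map_chr(.data$chain_ids, paste, collapse = ",")
    )
}

write_reports <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) {
    readr::write_tsv(x, file.path(out_dir, name), progress = FALSE)
  }
  w(as_tibble(result$index), "genes_ranked.tsv")
  w(flatten_chain_table(result$chains), "chains.tsv")
  w(flatten_chain_table(result$significant), "significant_chains.tsv")
  w(flatten_paracluster_table(result$paraclusters), "paraclusters.tsv")
  w(result$metrics$summary, "summary.tsv")
  w(result$metrics$size_distribution, "size_distribution.tsv")
  w(result$metrics$adjacency, "adjacency.tsv")
  ov <- as_tibble(result$overlap, rownames = "dataset")
  w(ov, "overlap_matrix.tsv")
  w(result$audit$per_dataset, "coverage_by_dataset.tsv")
  w(result$audit$per_chromosome, "coverage_by_chromosome.tsv")
  if (!is.null(result$walk)) {
    prof <- result$walk$profile |>
      left_join(result$walk$baseline, by = c("dataset", "span")) |>
      rename(observed_count = "count", permuted_mean = "mean_count")
    w(prof, "walk_profile.tsv")
    w(result$walk$nearest, "nearest_histogram.tsv")
  }
  jsonlite::write_json(
    list(
      summary = result$metrics$summary,
      adjacency = result$metrics$adjacency
    ),
    file.path(out_dir, "summary.json"),
    dataframe = "rows", digits = NA, pretty = TRUE
  )
  cfg <- result$config
  prov <- list(
    package = "paraclust",
    parameters = list(
      max_span = cfg$max_span, max_gap = cfg$max_gap,
      max_gaps = if (is.finite(cfg$max_gaps)) cfg$max_gaps else "unlimited",
      collapse_nested = cfg$collapse_nested,
      e_threshold = cfg$e_threshold,
      n_permutations = cfg$n_permutations,
      do_walk = cfg$do_walk,
      seed = cfg$seed
    ),
    inputs = list(
      n_genes = nrow(result$index),
      datasets = sort(unique(result$annotations$dataset)),
      gene_table_hash = rlang::hash(as_tibble(result$index)),
      annotation_hash = rlang::hash(result$annotations)
    )
  )
  yaml::write_yaml(prov, file.path(out_dir, "provenance.yaml"))
  invisible(out_dir)
}

split_ints <- function(x) lapply(strsplit(x, ",", fixed = TRUE), function(v) {
  if (length(v) == 1 && (is.na(v) || v == "")) integer(0) else as.integer(v)
})
split_chrs <- function(x) lapply(strsplit(x, ",", fixed = TRUE), function(v) {
  if (length(v) == 1 && (is.na(v) || v == "")) character(0) else v
})

#' Read back a flattened chain or paracluster table
#'
#' Inverse of the TSV writers used by [run_pipeline()]: comma-separated
#' list columns are restored, so pipeline stages can be composed from files.
#'
#' @param path TSV path written by the pipeline (`chains.tsv`,
#'   `significant_chains.tsv` or `paraclusters.tsv`).
#' @return a `chain_table` / `paracluster_table` tibble.
#' @export
read_chain_table <- function(path) {
  tab <- readr::read_tsv(
    path,
    col_types = readr::cols(
      members = readr::col_character(),
      member_genes = readr::col_character(),
      common_terms = readr::col_character(),
      gap_start = readr::col_character(),
      gap_raw = readr::col_character(),
      gap_eff = readr::col_character(),
      dataset = readr::col_character(),
      chromosome = readr::col_character(),
      chain_id = readr::col_character()
    ),
    show_col_types = FALSE, progress = FALSE
  )
  tab |>
    mutate(
      members = split_ints(.data$members),
      member_genes = split_chrs(.data$member_genes),
      common_terms = split_chrs(.data$common_terms),
      gap_start = split_ints(.data$gap_start),
      gap_raw = split_ints(.data$gap_raw),
      gap_eff = split_ints(.data$gap_eff)
    )
}

#' @rdname read_chain_table
#' @export
read_paracluster_table <- function(path) {
  tab <- readr::read_tsv(
    path,
    col_types = readr::cols(
      member_ranks = readr::col_character(),
      member_gene_ids = readr::col_character(),
      interstitial_gene_ids = readr::col_character(),
      datasets = readr::col_character(),
      chain_ids = readr::col_character(),
      cluster_id = readr::col_character(),
      chromosome = readr::col_character()
    ),
    show_col_types = FALSE, progress = FALSE
  )
  tab |>
    mutate(
      member_ranks = split_ints(.data$member_ranks),
      member_gene_ids = split_chrs(.data$member_gene_ids),
      interstitial_gene_ids = split_chrs(.data$interstitial_gene_ids),
      datasets = split_chrs(.data$datasets),
      chain_ids = split_chrs(.data$chain_ids)
    )
}

#' @export
print.paraclust_result <- function(x, ...) {
  cat("paraclust pipeline result\n")
  cat("  genes:", nrow(x$index), "\n")
  cat("  datasets:", paste(sort(unique(x$annotations$dataset)), collapse = ", "), "\n")
  cat("  candidate chains:", nrow(x$chains), "\n")
  cat("  significant chains (e <", x$config$e_threshold, "):", nrow(x$significant), "\n")
  cat("  merged paraclusters:", nrow(x$paraclusters), "\n")
  merged <- x$metrics$summary[x$metrics$summary$dataset == "merged", ]
  if (nrow(merged) == 1) {
    cat(sprintf("  genes in paraclusters: %d (%.1f%%)\n",
                merged$genes_in_paraclusters, merged$percent_genes))
  }
  invisible(x)
}
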