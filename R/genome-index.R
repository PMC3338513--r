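#' Natural-sort order for chromosome names
#'
#' Orders chromosome names the way a geneticist reads them: numeric suffixes
#' ascend numerically (chr2 before chr10), names without a numeric suffix
#' (chrX, chrMT, scaffolds) follow alphabetically.
#'
#' @param x character vector of chromosome names (duplicates allowed).
#' @return unique chromosome names in natural order.
#' @export
#' @examples
#' natural_chromosome_order(c("chr10", "chr2", "chrX", "chr1"))
natural_chromosome_order <- function(x) {
  u <- unique(as.character(x))
  has_num <- grepl("[0-9]+$", u)
  prefix <- ifelse(has_num, sub("[0-9]+$", "", u), u)
  num <- rep(Inf, length(u))
  num[has_num] <- as.numeric(sub("^.*?([0-9]+)$", "\\1", u[has_num]))
  u[order(prefix, num, u, method = "radix")]
}

#' Build a rank-ordered genome index
#'
#' Places genes in rank order by their locations along chromosomes, beginning
#' with the first gene of the first chromosome and proceeding chromosome by
#' chromosome. All downstream proximity statistics use this rank order rather
#' than base-pair coordinates, which avoids artifacts from variable gene
#' density and keeps only relative positioning.
#'
#' Ties in start coordinate are broken by end coordinate, then by gene id, so
#' the index is deterministic. Overlapping gene models are kept as distinct
#' ranked loci.
#'
#' @param genes data frame with columns `gene_id`, `chromosome`, `start`,
#'   `end` and optionally `strand`. Coordinates are 1-based closed.
#' @param chromosome_order optional character vector giving the order in
#'   which chromosomes are concatenated. Defaults to
#'   [natural_chromosome_order()] of the chromosomes present. Every
#'   chromosome in `genes` must appear in it.
#' @return a `genome_index` tibble: the input columns plus `rank`
#'   (genome-wide position, `1..N`) and `chrom_rank` (position within the
#'   chromosome).
#' @export
#' @examples
#' g <- tibble::tibble(
#'   gene_id = c("a", "b", "c"), chromosome = "chr1",
#'   start = c(100, 50, 200), end = c(150, 80, 260)
#' )
#' build_gene_index(g)
build_gene_index <- function(genes, chromosome_order = NULL) {
  genes <- as_tibble(genes)
  req <- c("gene_id", "chromosome", "start", "end")
  miss <- setdiff(req, names(genes))
  if (length(miss) > 0) {
    abort(paste0("gene table is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (!"strand" %in% names(genes)) genes$strand <- "+"
  genes <- mutate(genes,
    gene_id = as.character(.data$gene_id),
    chromosome = as.character(.data$chromosome),
    start = as.integer(.data$start), end = as.integer(.data$end)
  )
  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate gene_id: ", paste(unique(dup), collapse = ", ")))
  }
  if (any(is.na(genes$start)) || any(is.na(genes$end)) || any(genes$end < genes$start)) {
    abort("invalid coordinates: start/end must be non-missing with end >= start")
  }
  chroms <- unique(genes$chromosome)
  if (is.null(chromosome_order)) {
    chromosome_order <- natural_chromosome_order(chroms)
  } else {
    unknown <- setdiff(chroms, chromosome_order)
    if (length(unknown) > 0) {
      abort(paste0(
        "chromosome(s) absent from chromosome_order: ",
        paste(unknown, collapse = ", ")
      ))
    }
  }
  idx <- genes |>
    mutate(.chrom = factor(.data$chromosome, levels = chromosome_order)) |>
    arrange(.data$.chrom, .data$start, .data$end, .data$gene_id) |>
    mutate(rank = row_number()) |>
    group_by(.data$.chrom) |>
    mutate(chrom_rank = row_number()) |>
    ungroup() |>
    select(-".chrom") |>
    select("gene_id", "chromosome", "start", "end", "strand", "rank", "chrom_rank")
  attr(idx, "chromosome_order") <- intersect(chromosome_order, chroms)
  class(idx) <- c("genome_index", class(idx))
  idx
}

#' Chromosome spans of a genome index
#'
#' @param index a `genome_index` from [build_gene_index()].
#' @return tibble with one row per chromosome: `chromosome`, `first_rank`,
#'   `last_rank`, `n_genes`. Spans partition `1..N` in concatenation order.
#' @export
chromosome_spans <- function(index) {
  index |>
    group_by(.data$chromosome) |>
    summarise(
      first_rank = min(.data$rank),
      last_rank = max(.data$rank),
      n_genes = n(),
      .groups = "drop"
    ) |>
    arrange(.data$first_rank)
}

validate_genome_index <- function(index) {
  stopifnot(is.data.frame(index))
  n <- nrow(index)
  if (!identical(sort(index$rank), seq_len(n))) {
    abort("genome index ranks are not a permutation of 1..N")
  }
  invisible(index)
}

#' Read a gene position table
#'
#' Reads gene loci from TSV (columns `gene_id`, `chromosome`, `start`, `end`,
#' optionally `strand`; 1-based closed coordinates), BED (0-based half-open,
#' converted to 1-based closed) or GFF3 (feature type `gene`, `ID`
#' attribute). BED and GFF3 parsing use rtracklayer.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"tsv"`, `"bed"` or `"gff3"`.
#' @return tibble suitable for [build_gene_index()].
#' @export
read_gene_table <- function(path, format = c("auto", "tsv", "bed", "gff3")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("gene table not found: ", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      bed = "bed",
      gff = "gff3", gff3 = "gff3",
      "tsv"
    )
  }
  if (format == "tsv") {
    tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    return(as_tibble(tab))
  }
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("reading BED/GFF3 requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3")
  df <- as.data.frame(gr)
  if (format == "gff3") {
    if ("type" %in% names(df)) df <- df[df$type == "gene", , drop = FALSE]
    id <- if ("ID" %in% names(df)) df$ID else df$Name
  } else {
    id <- df$name
  }
  tibble(
    gene_id = as.character(id),
    chromosome = as.character(df$seqnames),
    start = as.integer(df$start), # rtracklayer already converts BED to 1-based
    end = as.integer(df$end),
    strand = as.character(df$strand)
  )
}

#' Read a term-based annotation table
#'
#' One row per gene-term assignment: columns `dataset`, `gene_id`, `term_id`.
#' A gene may carry zero, one or many terms in a dataset.
#'
#' @param path TSV file path.
#' @return tibble with columns `dataset`, `gene_id`, `term_id`.
#' @export
read_annotation_table <- function(path) {
  if (!file.exists(path)) abort(paste0("annotation table not found: ", path))
  tab <- readr::read_tsv(path,
    col_types = readr::cols(.default = readr::col_character()),
    show_col_types = FALSE, progress = FALSE
  )
  miss <- setdiff(c("dataset", "gene_id", "term_id"), names(tab))
  if (length(miss) > 0) {
    abort(paste0("annotation table missing column(s): ", paste(miss, collapse = ", ")))
  }
  as_tibble(tab[, c("dataset", "gene_id", "term_id")])
}

#' Read a pairwise paralogy table
#'
#' Columns `dataset`, `gene_id_1`, `gene_id_2`, one unordered pair per row
#' (e.g. explicitly asserted paralog pairs).
#'
#' @param path TSV file path.
#' @return tibble with columns `dataset`, `gene_id_1`, `gene_id_2`.
#' @export
read_paralog_pairs <- function(path) {
  if (!file.exists(path)) abort(paste0("paralog pair table not found: ", path))
  tab <- readr::read_tsv(path,
    col_types = readr::cols(.default = readr::col_character()),
    show_col_types = FALSE, progress = FALSE
  )
  miss <- setdiff(c("dataset", "gene_id_1", "gene_id_2"), names(tab))
  if (length(miss) > 0) {
    abort(paste0("paralog pair table missing column(s): ", paste(miss, collapse = ", ")))
  }
  as_tibble(tab[, c("dataset", "gene_id_1", "gene_id_2")])
}

#' Convert pairwise paralogy assertions into family terms
#'
#' Treats the pairwise evidence as an undirected graph and assigns one
#' synthetic term per connected component, so that pair-derived datasets can
#' be processed with the same machinery as term-based datasets. Term ids are
#' canonicalised by the lexicographically smallest member gene id, making the
#' result independent of pair order.
#'
#' @param pairs tibble with columns `dataset`, `gene_id_1`, `gene_id_2`.
#' @param index a `genome_index`; every paired gene must be present.
#' @return annotation tibble with columns `dataset`, `gene_id`, `term_id`.
#' @export
pairs_to_families <- function(pairs, index) {
  pairs <- as_tibble(pairs)
  if (nrow(pairs) == 0) {
    return(tibble(dataset = character(), gene_id = character(), term_id = character()))
  }
  if (any(pairs$gene_id_1 == pairs$gene_id_2)) {
    abort("self-pairs are not allowed in a paralog pair set")
  }
  unknown <- setdiff(
    unique(c(pairs$gene_id_1, pairs$gene_id_2)),
    index$gene_id
  )
  if (length(unknown) > 0) {
    abort(paste0(
      "paired gene(s) absent from the genome index: ",
      paste(head(unknown, 10), collapse = ", "),
      if (length(unknown) > 10) sprintf(" (and %d more)", length(unknown) - 10) else ""
    ))
  }
  pairs |>
    group_by(.data$dataset) |>
    group_modify(function(p, key) {
      g <- igraph::graph_from_data_frame(
        p[, c("gene_id_1", "gene_id_2")],
        directed = FALSE
      )
      comp <- igraph::components(g)
      members <- split(names(comp$membership), comp$membership)
      purrr::map_dfr(members, function(m) {
        tibble(gene_id = sort(m), term_id = paste0("fam:", min(m)))
      })
    }) |>
    ungroup() |>
    arrange(.data$dataset, .data$term_id, .data$gene_id)
}

#' Genome-wide term frequencies
#'
#' Counts, for every annotation term in every dataset, the number of genes in
#' the genome carrying it (`m`). A gene carrying a term more than once counts
#' once. `m` is the success count of the hypergeometric model used to score
#' chains.
#'
#' @param annotations tibble with columns `dataset`, `gene_id`, `term_id`.
#' @return tibble with columns `dataset`, `term_id`, `m`.
#' @export
term_frequencies <- function(annotations) {
  annotations |>
    distinct(.data$dataset, .data$gene_id, .data$term_id) |>
    count(.data$dataset, .data$term_id, name = "m") |>
    arrange(.data$dataset, .data$term_id)
}

#' Write / read a genome index as TSV
#'
#' Round-trips exactly: ranks, coordinates and chromosome order are
#' preserved.
#'
#' @param index a `genome_index`.
#' @param path file path.
#' @return `path`, invisibly (write) or a `genome_index` (read).
#' @export
write_genome_index <- function(index, path) {
  readr::write_tsv(as_tibble(index), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_genome_index
#' @export
read_genome_index <- function(path) {
  tab <- readr::read_tsv(path,
    col_types = readr::cols(
      gene_id = readr::col_character(),
      chromosome = readr::col_character(),
      start = readr::col_integer(),
      end = readr::col_integer(),
      strand = readr::col_character(),
      rank = readr::col_integer(),
      chrom_rank = readr::col_integer()
    ),
    show_col_types = FALSE, progress = FALSE
  )
  idx <- arrange(as_tibble(tab), .data$rank)
  attr(idx, "chromosome_order") <- unique(idx$chromosome)
  class(idx) <- c("genome_index", class(idx))
  idx
}
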