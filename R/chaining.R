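#' Chaining configuration
#'
#' Parameters of the greedy annotation-chaining scan. The gap length is the
#' number of consecutive genes inside a chain that share none of the chain's
#' common annotations; a run longer than `max_gap` closes the chain. The
#' default of 15 reflects the empirical observation that varying the allowed
#' gap has its largest effect at small values and essentially none beyond
#' 14-15. Limiting the total number of gaps is not critical to the amount of
#' clustering detected, so `max_gaps` defaults to unlimited.
#'
#' @param max_gap largest effective gap (run of non-sharing genes) allowed
#'   inside a chain. Default 15.
#' @param max_gaps largest number of gaps allowed per chain, or `Inf`.
#' @param collapse_nested if `TRUE` (default), a maximal run of interstitial
#'   genes that are all members of a single other chain (a nested tandem
#'   array of a different family) counts as one gap space instead of its raw
#'   length, and chaining is re-run to a fixed point.
#' @param max_collapse_iter iteration cap for the fixed-point re-run.
#' @return a `chaining_config` list.
#' @export
chaining_config <- function(max_gap = 15, max_gaps = Inf,
                            collapse_nested = TRUE, max_collapse_iter = 5) {
  stopifnot(max_gap >= 0, max_gaps >= 0, max_collapse_iter >= 1)
  structure(
    list(
      max_gap = as.integer(max_gap),
      max_gaps = if (is.finite(max_gaps)) as.integer(max_gaps) else Inf,
      collapse_nested = isTRUE(collapse_nested),
      max_collapse_iter = as.integer(max_collapse_iter)
    ),
    class = "chaining_config"
  )
}

# Per-dataset preparation: integer term codes per rank, in chromosome order.
prep_term_lists <- function(index, annotations) {
  n <- nrow(index)
  ann <- annotations |>
    distinct(.data$dataset, .data$gene_id, .data$term_id)
  unknown <- setdiff(unique(ann$gene_id), index$gene_id)
  if (length(unknown) > 0) {
    abort(paste0(
      "annotated gene(s) absent from the genome index: ",
      paste(head(unknown, 10), collapse = ", "),
      if (length(unknown) > 10) sprintf(" (and %d more)", length(unknown) - 10) else ""
    ))
  }
  rank_of <- setNames(index$rank, index$gene_id)
  ann$rank <- unname(rank_of[ann$gene_id])
  datasets <- sort(unique(ann$dataset))
  lapply(setNames(datasets, datasets), function(ds) {
    a <- ann[ann$dataset == ds, ]
    lev <- sort(unique(a$term_id))
    code <- match(a$term_id, lev)
    by_rank <- split(code, factor(a$rank, levels = seq_len(n)))
    by_rank <- lapply(by_rank, function(v) sort(unique(as.integer(v))))
    list(levels = lev, terms = by_rank)
  })
}

# Build per-rank sorted chain-id membership lists from a chain table.
nest_from_chains <- function(chains, n) {
  empty <- rep(list(integer(0)), n)
  if (is.null(chains) || nrow(chains) == 0) return(empty)
  ranks <- unlist(chains$members, use.names = FALSE)
  ids <- rep(seq_len(nrow(chains)), lengths(chains$members))
  got <- split(ids, factor(ranks, levels = seq_len(n)))
  lapply(got, function(v) sort(as.integer(v)))
}

run_chain_pass <- function(index, prep, spans, config, nest) {
  rows <- list()
  for (ds in names(prep)) {
    lev <- prep[[ds]]$levels
    terms <- prep[[ds]]$terms
    for (ci in seq_len(nrow(spans))) {
      first <- spans$first_rank[ci]
      last <- spans$last_rank[ci]
      res <- scan_chromosome_cpp(
        terms[first:last], nest[first:last],
        config$max_gap,
        if (is.finite(config$max_gaps)) config$max_gaps else -1L
      )
      if (length(res) == 0) next
      for (ch in res) {
        members <- ch$members + first - 1L
        rows[[length(rows) + 1L]] <- list(
          dataset = ds,
          chromosome = spans$chromosome[ci],
          start_rank = members[1],
          end_rank = members[length(members)],
          l = length(members),
          k = members[length(members)] - members[1] + 1L,
          members = members,
          common_terms = lev[ch$common],
          gap_start = ch$gap_start + first - 1L,
          gap_raw = ch$gap_raw,
          gap_eff = ch$gap_eff
        )
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble(
      dataset = character(), chromosome = character(),
      start_rank = integer(), end_rank = integer(),
      l = integer(), k = integer(),
      members = list(), common_terms = list(),
      gap_start = list(), gap_raw = list(), gap_eff = list()
    ))
  }
  tibble(
    dataset = map_chr(rows, "dataset"),
    chromosome = map_chr(rows, "chromosome"),
    start_rank = map_int(rows, "start_rank"),
    end_rank = map_int(rows, "end_rank"),
    l = map_int(rows, "l"),
    k = map_int(rows, "k"),
    members = map(rows, "members"),
    common_terms = map(rows, "common_terms"),
    gap_start = map(rows, "gap_start"),
    gap_raw = map(rows, "gap_raw"),
    gap_eff = map(rows, "gap_eff")
  ) |>
    arrange(.data$dataset, .data$start_rank)
}

chain_signature <- function(chains) {
  sort(paste(chains$dataset, map_chr(chains$members, paste, collapse = ",")))
}

#' Detect candidate chains of annotation-sharing genes
#'
#' Runs the greedy forward chaining scan separately for every annotation
#' dataset, chromosome by chromosome. A chain opens at the first unassigned
#' annotated gene; the scan admits the nearest downstream unassigned gene
#' sharing at least one of the chain's current common annotations, provided
#' the interstitial run does not exceed the gap limit; on admission the
#' common subset is intersected with the new member's terms, so the chain is
#' represented by the least common subset of annotations shared by all its
#' members. A gene joins at most one chain per dataset, and chains never
#' cross chromosome boundaries.
#'
#' With `collapse_nested = TRUE`, gap lengths are recomputed so that a
#' maximal run of interstitial genes that are all members of a single other
#' chain (from any dataset of the run) counts as one gap space - nested
#' tandem arrays of a different family do not break up the surrounding
#' chain - and the scan is re-run until chain boundaries stop changing
#' (bounded by `max_collapse_iter`; a warning is issued if the bound is hit).
#'
#' @param index a `genome_index`.
#' @param annotations annotation tibble (`dataset`, `gene_id`, `term_id`);
#'   may hold several datasets. Pair-derived evidence should first pass
#'   through [pairs_to_families()].
#' @param config a [chaining_config()].
#' @return a `chain_table` tibble: `dataset`, `chromosome`, `chain_id`,
#'   `start_rank`, `end_rank`, `l` (member count), `k` (span including
#'   interstitials), list-columns `members` (ranks), `member_genes`,
#'   `common_terms`, `gap_start`, `gap_raw`, `gap_eff`.
#' @export
detect_chains <- function(index, annotations, config = chaining_config()) {
  validate_genome_index(index)
  prep <- prep_term_lists(index, annotations)
  spans <- chromosome_spans(index)
  n <- nrow(index)

  empty_nest <- rep(list(integer(0)), n)
  chains <- run_chain_pass(index, prep, spans, config, empty_nest)

  if (config$collapse_nested && nrow(chains) > 0) {
    prev_sig <- chain_signature(chains)
    converged <- FALSE
    for (it in seq_len(config$max_collapse_iter)) {
      nest <- nest_from_chains(chains, n)
      chains2 <- run_chain_pass(index, prep, spans, config, nest)
      sig <- chain_signature(chains2)
      chains <- chains2
      if (identical(sig, prev_sig)) {
        converged <- TRUE
        break
      }
      prev_sig <- sig
    }
    if (!converged) {
      warning("nested-gap collapsing did not reach a fixed point; keeping last stable result")
    }
  }

  if (nrow(chains) > 0) {
    chains <- chains |>
      group_by(.data$dataset) |>
      mutate(chain_id = paste0(.data$dataset, ":", row_number())) |>
      ungroup() |>
      mutate(member_genes = map(.data$members, ~ index$gene_id[.x])) |>
      select(
        "dataset", "chromosome", "chain_id", "start_rank", "end_rank",
        "l", "k", "members", "member_genes", "common_terms",
        "gap_start", "gap_raw", "gap_eff"
      )
  } else {
    chains$chain_id <- character(0)
    chains$member_genes <- list()
  }
  attr(chains, "config") <- config
  attr(chains, "n_genes") <- n
  class(chains) <- c("chain_table", class(chains))
  chains
}
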