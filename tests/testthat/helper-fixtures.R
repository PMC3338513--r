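# Hand-built fixtures and independent brute-force oracles used across tests.

mk_genes <- function(n, chromosome = "chr1", prefix = "g", start0 = 0L) {
  tibble::tibble(
    gene_id = sprintf("%s%03d", prefix, seq_len(n)),
    chromosome = chromosome,
    start = start0 + seq_len(n) * 100L,
    end = start0 + seq_len(n) * 100L + 50L
  )
}

mk_index <- function(n, ...) build_gene_index(mk_genes(n, ...))

mk_ann <- function(gene_id, term_id, dataset = "d1") {
  tibble::tibble(dataset = dataset, gene_id = gene_id, term_id = term_id)
}

# exact hypergeometric upper tail by exhaustive integer-binomial summation
oracle_hyper_tail <- function(N, m, k, l) {
  hi <- min(k, m)
  if (l > hi) return(0)
  i <- l:hi
  sum(choose(m, i) * choose(N - m, k - i)) / choose(N, k)
}

# all-pairs chromosome walk, O(N * max_span) double loop
oracle_profile <- function(index, annotations, max_span) {
  ann <- dplyr::distinct(annotations, dataset, gene_id, term_id)
  out <- list()
  for (ds in sort(unique(ann$dataset))) {
    terms <- split(ann$term_id[ann$dataset == ds], ann$gene_id[ann$dataset == ds])
    counts <- stats::setNames(integer(max_span - 1), 2:max_span)
    for (i in seq_len(nrow(index))) {
      for (n in 2:max_span) {
        j <- i + n - 1
        if (j > nrow(index)) next
        if (index$chromosome[j] != index$chromosome[i]) next
        ti <- terms[[index$gene_id[i]]]
        tj <- terms[[index$gene_id[j]]]
        if (!is.null(ti) && !is.null(tj) && length(intersect(ti, tj)) > 0) {
          counts[as.character(n)] <- counts[as.character(n)] + 1L
        }
      }
    }
    out[[ds]] <- tibble::tibble(dataset = ds, span = 2:max_span,
                                count = as.integer(counts))
  }
  dplyr::bind_rows(out)
}

# connected components by plain union-find over gene-id pairs
oracle_components <- function(g1, g2) {
  nodes <- sort(unique(c(g1, g2)))
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (i in seq_along(g1)) {
    r1 <- find(g1[i]); r2 <- find(g2[i])
    if (r1 != r2) parent[[r2]] <- r1
  }
  roots <- vapply(nodes, find, character(1))
  split(nodes, roots)
}

# small, fast generator configuration for unit tests
tiny_sim_config <- function(seed = 1, ...) {
  args <- list(
    n_genes = 2000,
    chromosome_weights = c(5, 3, 2, 0.3),
    n_large_families = 5, large_family_genes = 90, large_family_max = 40,
    n_planted = 12, planted_size_range = c(3, 8),
    high_freq_domains = c(hf_dom_1 = 40),
    seed = seed
  )
  extra <- list(...)
  for (nm in names(extra)) args[nm] <- list(extra[[nm]])
  do.call(sim_config, args)
}
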