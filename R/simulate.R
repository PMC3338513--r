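#' Configuration for the synthetic-genome generator
#'
#' Describes a genome of `n_genes` distributed over chromosomes with a
#' skewed size distribution (including micro-chromosomes), a
#' singleton-dominated family-size mixture with a small number of very
#' large families, planted paraclusters (tandem or gapped, occasionally
#' with a nested array of a different family inside a gap), several
#' annotation datasets derived from the true families with per-dataset
#' dropout, and high-frequency domains sprinkled on dispersed genes.
#'
#' The defaults emulate the human genome's published annotation structure:
#' roughly 68% of genes are family singletons, multi-gene families average
#' about 3 members, and close to 900 genes sit in a few dozen families of
#' more than 10 members, the largest of order 400. Dropout models the
#' incomplete annotation coverage of any single dataset, which is why
#' merging datasets recovers clusters each one alone misses; the
#' high-frequency domains exercise the false-negative regime of prolific
#' domains and the "gravitational" inclusion risk.
#'
#' @param n_genes total gene count.
#' @param chromosome_weights relative chromosome sizes; defaults to a
#'   skewed 21-chromosome layout with two micro-chromosomes.
#' @param singleton_fraction fraction of genes that are family singletons.
#' @param small_family_mean,small_family_max mean and maximum size of small
#'   multi-gene families (truncated geometric).
#' @param n_large_families,large_family_genes,large_family_max cap on the
#'   number of large (size >= 10) families, the approximate total number of
#'   genes they hold, and the maximum family size.
#' @param n_planted number of planted clusters.
#' @param planted_size_range inclusive range of planted cluster sizes
#'   (paralog members).
#' @param gapped_fraction fraction of planted clusters carrying gaps.
#' @param max_planted_gap largest planted gap length.
#' @param max_gaps_per_cluster largest number of gaps per planted cluster.
#' @param nested_fraction fraction of gapped clusters whose first gap is
#'   filled by a nested tandem array of a different family.
#' @param datasets named character vector: names are dataset names, values
#'   their kind (`"domain"` or `"family"`); high-frequency domains are only
#'   added to domain-kind datasets.
#' @param pair_dataset name of the emitted pairwise-paralogy dataset.
#' @param dropout probability that a gene's true annotation is missing from
#'   a given dataset (independently per dataset); in the pairwise dataset a
#'   dropped gene contributes no pairs.
#' @param high_freq_domains named integer vector: domain id -> number of
#'   dispersed carrier genes.
#' @param seed integer seed; the generator is fully deterministic under it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_genes = 20000,
                       chromosome_weights = NULL,
                       singleton_fraction = 0.683,
                       small_family_mean = 3.1,
                       small_family_max = 9,
                       n_large_families = 48,
                       large_family_genes = 877,
                       large_family_max = 400,
                       n_planted = 100,
                       planted_size_range = c(3, 20),
                       gapped_fraction = 0.5,
                       max_planted_gap = 5,
                       max_gaps_per_cluster = 3,
                       nested_fraction = 0.1,
                       datasets = c(domains_a = "domain", domains_b = "domain",
                                    families_a = "family", families_b = "family"),
                       pair_dataset = "paralogs",
                       dropout = 0.1,
                       high_freq_domains = c(hf_dom_1 = 400, hf_dom_2 = 300),
                       seed = 1L) {
  stopifnot(
    n_genes >= 1,
    singleton_fraction >= 0, singleton_fraction <= 1,
    dropout >= 0, dropout < 1,
    n_planted >= 0,
    length(planted_size_range) == 2,
    planted_size_range[1] >= 2,
    planted_size_range[2] >= planted_size_range[1],
    max_planted_gap >= 1, nested_fraction >= 0, nested_fraction <= 1
  )
  if (is.null(chromosome_weights)) {
    chromosome_weights <- c(seq(10, 1, length.out = 19), 0.4, 0.25)
  }
  structure(
    list(
      n_genes = as.integer(n_genes),
      chromosome_weights = chromosome_weights,
      singleton_fraction = singleton_fraction,
      small_family_mean = small_family_mean,
      small_family_max = as.integer(small_family_max),
      n_large_families = as.integer(n_large_families),
      large_family_genes = as.integer(large_family_genes),
      large_family_max = as.integer(large_family_max),
      n_planted = as.integer(n_planted),
      planted_size_range = as.integer(planted_size_range),
      gapped_fraction = gapped_fraction,
      max_planted_gap = as.integer(max_planted_gap),
      max_gaps_per_cluster = as.integer(max_gaps_per_cluster),
      nested_fraction = nested_fraction,
      datasets = datasets,
      pair_dataset = pair_dataset,
      dropout = dropout,
      high_freq_domains = high_freq_domains,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# sample() that never interprets a length-1 x as 1:x
resample <- function(x, size = length(x), ...) {
  x[sample.int(length(x), size = size, ...)]
}

# integer apportionment of N over weights (largest remainders)
apportion <- function(n, weights) {
  raw <- weights / sum(weights) * n
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# truncated geometric sizes on 2..smax with the requested mean
small_family_probs <- function(mean_size, smax) {
  s <- 2:smax
  if (mean_size <= 2) return(c(1, rep(0, length(s) - 1)))
  f <- function(q) sum(s * q^(s - 2)) / sum(q^(s - 2)) - mean_size
  q <- stats::uniroot(f, c(1e-6, 1 - 1e-6))$root
  p <- q^(s - 2)
  p / sum(p)
}

#' Generate a synthetic genome with a ground-truth ledger
#'
#' Emits a gene position table, term-based annotation tables for every
#' configured dataset (after per-dataset dropout), a pairwise paralogy
#' table, and a truth ledger that exactly describes what was planted:
#' family memberships, planted cluster coordinates, high-frequency-domain
#' carriers and the post-dropout annotation tables. Deterministic under
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @return a `paraclust_sim` list with elements `genes`, `annotations`,
#'   `pairs` and `truth`.
#' @export
simulate_genome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_genome_impl(config))
}

simulate_genome_impl <- function(config) {
  n <- config$n_genes
  sizes <- apportion(n, config$chromosome_weights)
  sizes <- sizes[sizes > 0]
  chroms <- paste0("chr", seq_along(sizes))

  ## ---- planted cluster specs ----
  planted <- list()
  if (config$n_planted > 0) {
    for (i in seq_len(config$n_planted)) {
      size <- resample(config$planted_size_range[1]:config$planted_size_range[2], 1)
      gapped <- runif(1) < config$gapped_fraction
      gap_after <- integer(0)
      gap_len <- integer(0)
      nested <- FALSE
      if (gapped) {
        n_g <- resample(seq_len(min(config$max_gaps_per_cluster, size - 1)), 1)
        gap_after <- sort(resample(seq_len(size - 1), n_g))
        gap_len <- resample(seq_len(config$max_planted_gap), n_g, replace = TRUE)
        if (runif(1) < config$nested_fraction) {
          nested <- TRUE
          gap_len[1] <- resample(2:max(2, config$max_planted_gap), 1)
        }
      }
      planted[[i]] <- list(
        family = sprintf("pfam%03d", i), size = size,
        gap_after = gap_after, gap_len = gap_len, nested = nested,
        footprint = size + sum(gap_len)
      )
    }
  }

  ## ---- assign clusters to chromosomes and place them ----
  slot_family <- lapply(sizes, function(L) rep(NA_character_, L))
  committed <- rep(0L, length(sizes))
  assigned_chrom <- integer(length(planted))
  if (length(planted) > 0) {
    ord <- resample(seq_along(planted))
    for (i in ord) {
      f <- planted[[i]]$footprint
      ok <- which(committed + f <= sizes)
      if (length(ok) == 0) {
        abort("planted clusters do not fit on the configured chromosomes")
      }
      ci <- if (length(ok) == 1) ok else
        resample(ok, 1, prob = sizes[ok] - committed[ok])
      assigned_chrom[i] <- ci
      committed[ci] <- committed[ci] + f
    }
  }

  planted_rows <- list()
  nested_id <- 0L
  for (ci in seq_along(sizes)) {
    here <- which(assigned_chrom == ci)
    if (length(here) == 0) next
    here <- resample(here) # placement order along the chromosome
    k <- length(here)
    free <- sizes[ci] - sum(map_int(planted[here], "footprint"))
    u <- sort(sample.int(free + k, k))
    prev_foot <- 0L
    for (bi in seq_len(k)) {
      i <- here[bi]
      sp <- planted[[i]]
      start <- (u[bi] - bi) + prev_foot + 1L
      prev_foot <- prev_foot + sp$footprint
      # lay out member and gap slots
      pos <- start
      member_pos <- integer(0)
      for (mi in seq_len(sp$size)) {
        slot_family[[ci]][pos] <- sp$family
        member_pos <- c(member_pos, pos)
        pos <- pos + 1L
        gi <- match(mi, sp$gap_after)
        if (!is.na(gi)) {
          glen <- sp$gap_len[gi]
          if (sp$nested && gi == 1) {
            nested_id <- nested_id + 1L
            nfam <- sprintf("nfam%03d", nested_id)
            slot_family[[ci]][pos:(pos + glen - 1)] <- nfam
            planted_rows[[length(planted_rows) + 1L]] <- list(
              family = nfam, chromosome = chroms[ci],
              member_chrom_pos = pos:(pos + glen - 1),
              size = glen, nested = TRUE
            )
          } else {
            slot_family[[ci]][pos:(pos + glen - 1)] <- "FILL"
          }
          pos <- pos + glen
        }
      }
      planted_rows[[length(planted_rows) + 1L]] <- list(
        family = sp$family, chromosome = chroms[ci],
        member_chrom_pos = member_pos, size = sp$size, nested = FALSE
      )
    }
  }

  planted_members <- sum(map_int(planted_rows, "size"))
  n_fill <- sum(map_int(slot_family, function(v) sum(v == "FILL", na.rm = TRUE)))

  ## ---- dispersed family mixture ----
  n_singletons <- round(config$singleton_fraction * n)
  large_sizes <- integer(0)
  if (config$n_large_families > 0 && config$large_family_genes > 0) {
    s_range <- 10:config$large_family_max
    pr <- s_range^-2.5
    while (sum(large_sizes) < config$large_family_genes &&
           length(large_sizes) < config$n_large_families) {
      large_sizes <- c(large_sizes, resample(s_range, 1, prob = pr))
    }
    over <- sum(large_sizes) - config$large_family_genes
    if (over > 0 && large_sizes[length(large_sizes)] - over >= 10) {
      large_sizes[length(large_sizes)] <- large_sizes[length(large_sizes)] - over
    }
  }
  remaining <- n - n_singletons - planted_members - sum(large_sizes)
  if (remaining < 0) {
    abort("family mixture infeasible: singletons, large families and planted clusters exceed the genome size")
  }
  small_sizes <- integer(0)
  if (remaining > 0) {
    pr <- small_family_probs(config$small_family_mean, config$small_family_max)
    svals <- 2:config$small_family_max
    est <- ceiling(remaining / 2) + 10
    draws <- resample(svals, est, replace = TRUE, prob = pr)
    cum <- cumsum(draws)
    n_keep <- which(cum >= remaining)[1]
    small_sizes <- draws[seq_len(n_keep)]
    excess <- sum(small_sizes) - remaining
    if (excess > 0) {
      last <- small_sizes[n_keep] - excess
      if (last >= 2) {
        small_sizes[n_keep] <- last
      } else {
        small_sizes <- small_sizes[-n_keep]
        n_singletons <- n_singletons + (remaining - sum(small_sizes))
      }
    }
  }
  if (n_fill > n_singletons) {
    abort("not enough singleton genes to fill planted gaps")
  }

  ## ---- assign genes to slots ----
  singleton_fams <- sprintf("sing%05d", seq_len(n_singletons))
  large_fams <- rep(sprintf("lfam%03d", seq_along(large_sizes)), large_sizes)
  small_fams <- rep(sprintf("sfam%04d", seq_along(small_sizes)), small_sizes)

  fill_pool <- singleton_fams[seq_len(n_fill)]
  dispersed_pool <- c(
    if (n_fill < n_singletons) singleton_fams[(n_fill + 1):n_singletons] else character(0),
    large_fams, small_fams
  )
  dispersed_pool <- resample(dispersed_pool)

  fill_i <- 0L
  disp_i <- 0L
  for (ci in seq_along(sizes)) {
    v <- slot_family[[ci]]
    is_fill <- which(!is.na(v) & v == "FILL")
    if (length(is_fill) > 0) {
      v[is_fill] <- fill_pool[fill_i + seq_along(is_fill)]
      fill_i <- fill_i + length(is_fill)
    }
    is_open <- which(is.na(v))
    if (length(is_open) > 0) {
      v[is_open] <- dispersed_pool[disp_i + seq_along(is_open)]
      disp_i <- disp_i + length(is_open)
    }
    slot_family[[ci]] <- v
  }

  ## ---- gene table ----
  genes <- purrr::map2_dfr(seq_along(sizes), sizes, function(ci, L) {
    tibble(
      chromosome = chroms[ci],
      chrom_rank = seq_len(L),
      family_id = slot_family[[ci]]
    )
  }) |>
    mutate(
      rank = row_number(),
      gene_id = sprintf("g%05d", .data$rank),
      start = (.data$chrom_rank - 1L) * 3000L + 1L,
      end = .data$start + 1999L,
      strand = "+"
    )
  families <- genes |>
    transmute(.data$gene_id, .data$family_id,
      type = dplyr::case_when(
        grepl("^pfam", .data$family_id) ~ "planted",
        grepl("^nfam", .data$family_id) ~ "nested",
        grepl("^lfam", .data$family_id) ~ "large",
        grepl("^sfam", .data$family_id) ~ "small",
        TRUE ~ "singleton"
      )
    )
  gene_table <- genes |>
    select("gene_id", "chromosome", "start", "end", "strand")

  ## ---- planted truth with gene ids / ranks ----
  chrom_offset <- c(0L, cumsum(sizes))[seq_along(sizes)]
  names(chrom_offset) <- chroms
  planted_truth <- purrr::map_dfr(seq_along(planted_rows), function(i) {
    pr <- planted_rows[[i]]
    ranks <- chrom_offset[[pr$chromosome]] + pr$member_chrom_pos
    tibble(
      cluster_id = sprintf("plant%03d", i),
      family_id = pr$family,
      chromosome = pr$chromosome,
      start_rank = min(ranks), end_rank = max(ranks),
      size = pr$size, nested = pr$nested,
      member_ranks = list(as.integer(ranks)),
      member_gene_ids = list(sprintf("g%05d", ranks))
    )
  })
  if (nrow(planted_truth) == 0) {
    planted_truth <- tibble(
      cluster_id = character(), family_id = character(),
      chromosome = character(), start_rank = integer(),
      end_rank = integer(), size = integer(), nested = logical(),
      member_ranks = list(), member_gene_ids = list()
    )
  }

  ## ---- high-frequency domain carriers (dispersed genes only) ----
  hf <- config$high_freq_domains
  hf_rows <- tibble(gene_id = character(), term_id = character())
  if (length(hf) > 0) {
    dispersed_genes <- families$gene_id[families$type %in% c("singleton", "small", "large")]
    hf_rows <- purrr::map_dfr(seq_along(hf), function(i) {
      cnt <- min(hf[[i]], length(dispersed_genes))
      tibble(
        gene_id = sort(resample(dispersed_genes, cnt)),
        term_id = names(hf)[i]
      )
    })
  }

  ## ---- per-dataset annotations with dropout ----
  base_rows <- tibble(gene_id = families$gene_id, term_id = families$family_id)
  annotations <- purrr::map_dfr(seq_along(config$datasets), function(di) {
    ds <- names(config$datasets)[di]
    kind <- config$datasets[[di]]
    rows <- base_rows
    if (kind == "domain" && nrow(hf_rows) > 0) rows <- bind_rows(rows, hf_rows)
    keep <- runif(nrow(rows)) >= config$dropout
    tibble(dataset = ds, rows[keep, , drop = FALSE])
  }) |>
    arrange(.data$dataset, .data$gene_id, .data$term_id)

  ## ---- pairwise paralogy table ----
  # dropout acts at the gene level, as for the term datasets: a dropped gene
  # has no paralogy annotation, so none of its pairs are emitted
  multi <- families |>
    filter(.data$type != "singleton") |>
    group_by(.data$family_id) |>
    filter(n() >= 2) |>
    ungroup()
  multi <- multi[runif(nrow(multi)) >= config$dropout, , drop = FALSE]
  pair_list <- split(multi$gene_id, multi$family_id)
  pair_list <- pair_list[lengths(pair_list) >= 2]
  pairs <- purrr::map_dfr(pair_list, function(g) {
    g <- sort(g)
    cmb <- combn(g, 2)
    tibble(gene_id_1 = cmb[1, ], gene_id_2 = cmb[2, ])
  })
  pairs <- tibble(dataset = config$pair_dataset, pairs)

  structure(
    list(
      genes = gene_table,
      annotations = annotations,
      pairs = pairs,
      truth = list(
        config = config,
        families = families,
        planted = planted_truth,
        hf_carriers = hf_rows,
        annotations = annotations,
        pairs = pairs,
        chromosome_sizes = setNames(sizes, chroms)
      )
    ),
    class = "paraclust_sim"
  )
}

#' Simulate a cross-species ortholog map
#'
#' Links a stated fraction of planted clusters between two synthetic
#' genomes: members of a linked cluster pair are joined 1:1 as in-paralog
#' partners, emulating duplicates shared since the species' common
#' ancestor; the remaining clusters stay unlinked (species specific).
#'
#' @param truth_a,truth_b truth ledgers of two [simulate_genome()] runs.
#' @param conserved_fraction fraction of planted clusters to link.
#' @param seed integer seed.
#' @return tibble `gene_a`, `gene_b`, `relation`, with the linked cluster
#'   pairs recorded in attribute `linked_clusters`.
#' @export
simulate_ortholog_map <- function(truth_a, truth_b, conserved_fraction, seed = 1) {
  stopifnot(conserved_fraction >= 0, conserved_fraction <= 1)
  pa <- truth_a$planted
  pb <- truth_b$planted
  n_pairable <- min(nrow(pa), nrow(pb))
  n_link <- round(conserved_fraction * n_pairable)
  linked <- withr::with_seed(seed, sort(sample.int(n_pairable, n_link)))
  map <- purrr::map_dfr(linked, function(i) {
    ga <- pa$member_gene_ids[[i]]
    gb <- pb$member_gene_ids[[i]]
    k <- min(length(ga), length(gb))
    tibble(gene_a = ga[seq_len(k)], gene_b = gb[seq_len(k)],
           relation = "inparalog")
  })
  if (nrow(map) == 0) {
    map <- tibble(gene_a = character(), gene_b = character(),
                  relation = character())
  }
  attr(map, "linked_clusters") <- tibble(
    cluster_a = pa$cluster_id[linked], cluster_b = pb$cluster_id[linked]
  )
  map
}
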