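test_that("the generator is deterministic under its seed", {
  s1 <- simulate_genome(tiny_sim_config(seed = 3))
  s2 <- simulate_genome(tiny_sim_config(seed = 3))
  expect_identical(s1$genes, s2$genes)
  expect_identical(s1$annotations, s2$annotations)
  expect_identical(s1$pairs, s2$pairs)
  # the coordinate grid is fixed; seeds move the content, not the loci
  s3 <- simulate_genome(tiny_sim_config(seed = 4))
  expect_false(identical(s1$annotations, s3$annotations))
})

test_that("the generator emits the exact configured gene count with ranks 1..N", {
  cfg <- sim_config(n_genes = 20686, seed = 2)
  sim <- simulate_genome(cfg)
  expect_equal(nrow(sim$genes), 20686L)
  idx <- build_gene_index(sim$genes)
  expect_identical(sort(idx$rank), 1:20686)
  # brute-force re-sort agrees with the assigned ranks
  ord <- order(
    match(sim$genes$chromosome, unique(sim$genes$chromosome)),
    sim$genes$start
  )
  expect_identical(idx$gene_id, sim$genes$gene_id[ord])
})

test_that("emitted term frequencies equal the ledger after dropout, exactly", {
  sim <- simulate_genome(tiny_sim_config(seed = 5, dropout = 0))
  fr <- term_frequencies(sim$annotations)
  fam_sizes <- dplyr::count(sim$truth$families, family_id, name = "size")
  for (ds in names(tiny_sim_config()$datasets)) {
    sub <- fr[fr$dataset == ds & !grepl("^hf_", fr$term_id), ]
    expect_equal(
      sub$m,
      fam_sizes$size[match(sub$term_id, fam_sizes$family_id)]
    )
  }
  # high-frequency domains appear in domain-kind datasets at the ledger count
  hf <- fr[fr$term_id == "hf_dom_1", ]
  expect_setequal(hf$dataset, c("domains_a", "domains_b"))
  expect_equal(unique(hf$m), nrow(sim$truth$hf_carriers))
})

test_that("dropout removes the configured fraction of annotations", {
  cfg <- sim_config(n_genes = 10000, n_planted = 20, seed = 6)
  sim <- simulate_genome(cfg)
  per_ds <- dplyr::count(sim$annotations, dataset)
  # base rows per dataset: one family row per gene (+ hf rows for domains)
  expect_true(all(abs(per_ds$n / (10000 * 0.9) - 1) < 0.1))
  audit <- coverage_audit(build_gene_index(sim$genes), sim$annotations)
  expect_true(all(abs(audit$per_dataset$coverage - 0.9) < 0.02))
})

test_that("the family-size mixture matches its configuration", {
  sim <- simulate_genome(sim_config(n_genes = 20000, n_planted = 0, seed = 7))
  sizes <- table(table(sim$truth$families$family_id))
  n_singleton <- sizes[["1"]]
  expect_equal(n_singleton / 20000, 0.683, tolerance = 0.01)
  multi <- as.integer(names(sizes))[-1]
  counts <- as.integer(sizes)[-1]
  small <- multi >= 2 & multi <= 9
  expect_equal(
    sum(multi[small] * counts[small]) / sum(counts[small]),
    3.1,
    tolerance = 0.15
  )
  expect_true(any(multi >= 10)) # large families exist
  expect_lte(max(multi), 400)
})

test_that("planted clusters with all-singleton background share no terms", {
  cfg <- sim_config(
    n_genes = 300, chromosome_weights = c(2, 1),
    singleton_fraction = 1, n_large_families = 0, large_family_genes = 0,
    n_planted = 0, high_freq_domains = NULL, dropout = 0, seed = 8
  )
  sim <- simulate_genome(cfg)
  fr <- term_frequencies(sim$annotations)
  expect_true(all(fr$m == 1))
  expect_equal(nrow(sim$pairs), 0L)
})

test_that("a single planted tandem array is recovered end to end", {
  cfg <- sim_config(
    n_genes = 200, chromosome_weights = c(1),
    singleton_fraction = 0.9, n_large_families = 0, large_family_genes = 0,
    n_planted = 1, planted_size_range = c(5, 5), gapped_fraction = 0,
    high_freq_domains = NULL, dropout = 0, seed = 9
  )
  sim <- simulate_genome(cfg)
  expect_equal(nrow(sim$truth$planted), 1L)
  expect_equal(sim$truth$planted$size, 5L)
  idx <- build_gene_index(sim$genes)
  ch <- detect_chains(idx, sim$annotations[sim$annotations$dataset == "families_a", ])
  hit <- ch[vapply(ch$members, function(m)
    all(sim$truth$planted$member_ranks[[1]] %in% m), logical(1)), ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$l, 5L)
})

test_that("infeasible planted layouts are rejected", {
  cfg <- sim_config(
    n_genes = 60, chromosome_weights = c(1, 1),
    n_planted = 10, planted_size_range = c(15, 20), seed = 10
  )
  expect_error(simulate_genome(cfg), "do not fit")
})

test_that("the ortholog map links the configured fraction of planted clusters", {
  ta <- simulate_genome(tiny_sim_config(seed = 11))$truth
  tb <- simulate_genome(tiny_sim_config(seed = 12))$truth
  expect_equal(nrow(simulate_ortholog_map(ta, tb, 0, seed = 1)), 0L)
  full <- simulate_ortholog_map(ta, tb, 1, seed = 1)
  linked <- attr(full, "linked_clusters")
  expect_equal(nrow(linked), min(nrow(ta$planted), nrow(tb$planted)))
  half <- simulate_ortholog_map(ta, tb, 0.5, seed = 1)
  expect_equal(
    nrow(attr(half, "linked_clusters")),
    round(0.5 * min(nrow(ta$planted), nrow(tb$planted)))
  )
  expect_true(all(half$relation == "inparalog"))
  # linked genes really are members of the flagged clusters
  expect_true(all(half$gene_a %in% unlist(ta$planted$member_gene_ids)))
  expect_true(all(half$gene_b %in% unlist(tb$planted$member_gene_ids)))
})
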