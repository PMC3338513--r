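test_that("genome metrics report counts, percents and size distribution", {
  idx <- mk_index(100)
  ann <- dplyr::bind_rows(
    mk_ann(sprintf("g%03d", 1:3), "A", "d1"), # cluster of 3
    mk_ann(sprintf("g%03d", 50:53), "B", "d1") # cluster of 4
  )
  sig <- score_chains(detect_chains(idx, ann), ann, idx)
  pc <- merge_paraclusters(sig, idx)
  gm <- genome_metrics(pc, sig, idx)
  merged <- gm$summary[gm$summary$dataset == "merged", ]
  expect_equal(merged$paracluster_count, 2L)
  expect_equal(merged$genes_in_paraclusters, 7L)
  expect_equal(merged$percent_genes, 7)
  expect_equal(gm$size_distribution$size, c(3L, 4L))
  expect_equal(gm$size_distribution$n_clusters, c(1L, 1L))
  expect_equal(gm$size_distribution$genes_excl_interstitial, c(3L, 4L))
  # cumulative distribution reaches exactly percent_genes at the largest size
  expect_equal(max(gm$size_distribution$cumulative_percent_genes),
               merged$percent_genes)
  # all members are tandem here: all adjacent, hence all within 10
  expect_equal(gm$adjacency$n_genes, c(7L, 7L))
  expect_equal(gm$adjacency$percent, c(7, 7))
})

test_that("merged gene totals are at least every dataset's total", {
  sim <- simulate_genome(tiny_sim_config(seed = 21))
  idx <- build_gene_index(sim$genes)
  ann <- dplyr::bind_rows(sim$annotations, pairs_to_families(sim$pairs, idx))
  sig <- filter_significant(score_chains(detect_chains(idx, ann), ann, idx), 0.01)
  pc <- merge_paraclusters(sig, idx)
  gm <- genome_metrics(pc, sig, idx)
  merged <- gm$summary$genes_in_paraclusters[gm$summary$dataset == "merged"]
  per_ds <- gm$summary$genes_in_paraclusters[gm$summary$dataset != "merged"]
  expect_true(all(merged >= per_ds))
})

test_that("family clustering fractions cover the planted/dispersed split", {
  idx <- mk_index(60)
  ann <- dplyr::bind_rows(
    mk_ann(sprintf("g%03d", 1:4), "clustered_fam"),
    # dispersed members sit > max_gap apart so they never chain
    mk_ann(sprintf("g%03d", c(10, 30, 50)), "dispersed_fam")
  )
  sig <- filter_significant(score_chains(detect_chains(idx, ann), ann, idx), 0.05)
  pc <- merge_paraclusters(sig, idx)
  fr <- family_clustering_fractions(ann, pc)
  expect_equal(fr$fraction[fr$term_id == "clustered_fam"], 1)
  expect_equal(fr$fraction[fr$term_id == "dispersed_fam"], 0)
  expect_equal(fr$size[fr$term_id == "dispersed_fam"], 3L)
  h <- family_size_effect(fr, min_size = 3)
  expect_equal(sum(h$n_families), 2L)
  expect_equal(sum(h$n_families[grepl("^\\[0,", h$fraction_bin)]), 1L)
})

test_that("cluster sharing follows the in-paralog partner rule", {
  mk_pc <- function(sets) {
    tibble::tibble(
      cluster_id = paste0("pc", seq_along(sets)),
      member_gene_ids = sets
    )
  }
  a <- mk_pc(list(c("a1", "a2"), c("a3", "a4")))
  b <- mk_pc(list(c("b1", "b2")))
  # empty map: everything species specific
  empty <- tibble::tibble(gene_a = character(), gene_b = character(),
                          relation = character())
  cs <- cluster_sharing(a, b, empty)
  expect_equal(cs$fraction_shared, 0)
  expect_equal(cs$fraction_specific, 1)
  # perfect 1:1 map of one cluster
  m <- tibble::tibble(gene_a = c("a1", "a2"), gene_b = c("b1", "b2"),
                      relation = "inparalog")
  cs2 <- cluster_sharing(a, b, m)
  expect_equal(cs2$fraction_shared, 0.5)
  # out-paralog partners do not count under the default relation
  m_out <- dplyr::mutate(m, relation = "outparalog")
  expect_equal(cluster_sharing(a, b, m_out)$fraction_shared, 0)
  # monotone: adding pairs never decreases the shared fraction
  m_more <- dplyr::bind_rows(m, tibble::tibble(
    gene_a = "a3", gene_b = "b1", relation = "inparalog"
  ))
  expect_gte(cluster_sharing(a, b, m_more)$fraction_shared, cs2$fraction_shared)
  expect_error(cluster_sharing(a, b, dplyr::mutate(m, relation = "cousin")),
               "unknown relation")
})

test_that("threshold sweep totals are non-decreasing", {
  sim <- simulate_genome(tiny_sim_config(seed = 22))
  idx <- build_gene_index(sim$genes)
  sc <- score_chains(detect_chains(idx, sim$annotations), sim$annotations, idx)
  sw <- threshold_sweep(sc, idx, thresholds = c(0.01, 0.05, 0.1, 0.15))
  for (ds in unique(sw$dataset)) {
    expect_false(is.unsorted(sw$genes_in_paraclusters[sw$dataset == ds]))
  }
  # at a huge threshold every candidate chain passes
  sw_all <- threshold_sweep(sc, idx, thresholds = 1e6)
  per_ds <- table(sc$dataset)
  got <- sw_all[sw_all$dataset != "merged", ]
  expect_equal(got$paracluster_count, as.integer(per_ds[got$dataset]))
})
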