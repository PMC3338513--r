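test_that("a tandem array forms a single gap-free chain", {
  idx <- mk_index(10)
  ann <- mk_ann(c("g001", "g002", "g003"), "A")
  ch <- detect_chains(idx, ann)
  expect_equal(nrow(ch), 1L)
  expect_equal(ch$l, 3L)
  expect_equal(ch$k, 3L)
  expect_equal(ch$members[[1]], 1:3)
  expect_equal(length(ch$gap_raw[[1]]), 0L)
})

test_that("an interstitial gene becomes a recorded gap", {
  idx <- mk_index(10)
  ann <- mk_ann(c("g001", "g002", "g004"), "A")
  ch <- detect_chains(idx, ann)
  expect_equal(nrow(ch), 1L)
  expect_equal(ch$l, 3L)
  expect_equal(ch$k, 4L)
  expect_equal(ch$gap_raw[[1]], 1L)
  expect_equal(ch$gap_start[[1]], 3L)
})

test_that("a run longer than max_gap splits the family into two chains", {
  idx <- mk_index(20)
  ann <- mk_ann(c("g001", "g002", "g019", "g020"), "A")
  ch <- detect_chains(idx, ann) # 16 interstitials > 15
  expect_equal(nrow(ch), 2L)
  expect_equal(ch$l, c(2L, 2L))
  expect_equal(ch$members[[1]], 1:2)
  expect_equal(ch$members[[2]], 19:20)
  # at max_gap 16 they chain together
  ch2 <- detect_chains(idx, ann, chaining_config(max_gap = 16))
  expect_equal(nrow(ch2), 1L)
  expect_equal(ch2$l, 4L)
})

test_that("admission intersects the common subset and excludes non-sharers", {
  idx <- mk_index(5)
  ann <- dplyr::bind_rows(
    mk_ann("g001", "A"), mk_ann("g001", "B"),
    mk_ann("g002", "A"),
    mk_ann("g003", "B")
  )
  ch <- detect_chains(idx, ann)
  expect_equal(nrow(ch), 1L)
  expect_equal(ch$members[[1]], 1:2)
  expect_equal(ch$common_terms[[1]], "A")
})

test_that("chains never cross chromosome boundaries", {
  g <- dplyr::bind_rows(mk_genes(3, "chr1", "a"), mk_genes(3, "chr2", "b"))
  idx <- build_gene_index(g)
  ann <- mk_ann(idx$gene_id, "A")
  ch <- detect_chains(idx, ann)
  expect_equal(nrow(ch), 2L)
  expect_equal(sort(ch$chromosome), c("chr1", "chr2"))
})

test_that("a nested tandem array of another family counts as one gap space", {
  # family A at ranks 1,2 and 23,24; ranks 3..22 are one family-B chain
  idx <- mk_index(24)
  ann <- dplyr::bind_rows(
    mk_ann(sprintf("g%03d", c(1, 2, 23, 24)), "A"),
    mk_ann(sprintf("g%03d", 3:22), "B")
  )
  ch <- detect_chains(idx, ann)
  a <- ch[vapply(ch$common_terms, function(t) "A" %in% t, logical(1)), ]
  expect_equal(nrow(a), 1L)
  expect_equal(a$members[[1]], c(1L, 2L, 23L, 24L))
  expect_equal(a$gap_raw[[1]], 20L)
  expect_equal(a$gap_eff[[1]], 1L)
  # without collapsing the A family is split in two
  ch0 <- detect_chains(idx, ann, chaining_config(collapse_nested = FALSE))
  a0 <- ch0[vapply(ch0$common_terms, function(t) "A" %in% t, logical(1)), ]
  expect_equal(nrow(a0), 2L)
})

test_that("partially nested interstitial runs collapse only the chained part", {
  # 20 interstitials of which the first 10 form a B chain: effective gap
  # 1 (collapsed run) + 10 (unchained genes) = 11 <= 15, chain continues
  idx <- mk_index(24)
  ann <- dplyr::bind_rows(
    mk_ann(sprintf("g%03d", c(1, 2, 23, 24)), "A"),
    mk_ann(sprintf("g%03d", 3:12), "B")
  )
  ch <- detect_chains(idx, ann)
  a <- ch[vapply(ch$common_terms, function(t) "A" %in% t, logical(1)), ]
  expect_equal(a$members[[1]], c(1L, 2L, 23L, 24L))
  expect_equal(a$gap_eff[[1]], 11L)
})

test_that("collapsing is a no-op when no nested chains exist", {
  idx <- mk_index(30)
  ann <- mk_ann(sprintf("g%03d", c(1, 3, 7, 20, 22)), "A")
  with_c <- detect_chains(idx, ann, chaining_config(collapse_nested = TRUE))
  without <- detect_chains(idx, ann, chaining_config(collapse_nested = FALSE))
  expect_equal(with_c$members, without$members)
  expect_equal(with_c$gap_eff, without$gap_eff)
})

test_that("chain membership partitions genes within a dataset", {
  sim <- simulate_genome(tiny_sim_config(seed = 5))
  idx <- build_gene_index(sim$genes)
  ch <- detect_chains(idx, sim$annotations)
  for (ds in unique(ch$dataset)) {
    members <- unlist(ch$members[ch$dataset == ds], use.names = FALSE)
    expect_equal(anyDuplicated(members), 0L)
  }
  # every effective gap respects the configured maximum
  expect_true(all(unlist(ch$gap_eff) <= 15))
  expect_true(all(ch$l >= 2), info = "only chains with >= 2 members emitted")
  expect_true(all(ch$k >= ch$l))
})

test_that("detection is invariant to annotation row order", {
  sim <- simulate_genome(tiny_sim_config(seed = 6))
  idx <- build_gene_index(sim$genes)
  ann <- sim$annotations
  ch1 <- detect_chains(idx, ann)
  set.seed(1)
  ch2 <- detect_chains(idx, ann[sample(nrow(ann)), ])
  expect_equal(ch1$members, ch2$members)
  expect_equal(ch1$common_terms, ch2$common_terms)
})

test_that("planted tandem arrays are recovered with the correct member count", {
  sim <- simulate_genome(tiny_sim_config(seed = 7, gapped_fraction = 0,
                                         dropout = 0, high_freq_domains = NULL))
  idx <- build_gene_index(sim$genes)
  ch <- detect_chains(idx, sim$annotations[sim$annotations$dataset == "families_a", ])
  planted <- sim$truth$planted
  for (i in seq_len(nrow(planted))) {
    hit <- which(vapply(
      ch$members, function(m) all(planted$member_ranks[[i]] %in% m), logical(1)
    ))
    expect_equal(length(hit), 1L)
    expect_equal(ch$l[hit], planted$size[i])
  }
})

test_that("total chained genes grows with the allowed gap length", {
  sim <- simulate_genome(tiny_sim_config(seed = 8))
  idx <- build_gene_index(sim$genes)
  totals <- vapply(c(0, 1, 5, 15), function(g) {
    ch <- detect_chains(idx, sim$annotations, chaining_config(max_gap = g))
    length(unique(unlist(ch$members)))
  }, numeric(1))
  expect_false(is.unsorted(totals))
})

test_that("the max_gaps cap closes chains after the allowed gap count", {
  idx <- mk_index(10)
  ann <- mk_ann(sprintf("g%03d", c(1, 3, 5, 7)), "A")
  unlimited <- detect_chains(idx, ann)
  expect_equal(unlimited$l, 4L)
  capped <- detect_chains(idx, ann, chaining_config(max_gaps = 1))
  expect_equal(capped$l[1], 2L)
})
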