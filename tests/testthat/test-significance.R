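test_that("hypergeometric tail matches closed forms", {
  expect_equal(hypergeom_tail(10, 3, 3, 3), 1 / choose(10, 3), tolerance = 1e-14)
  expect_equal(hypergeom_tail(500, 40, 7, 0), 1) # certain event
  expect_equal(hypergeom_tail(20, 4, 5, 5), 0) # l > m: impossible draw
  expect_equal(
    hypergeom_tail(100, 10, 6, 3),
    oracle_hyper_tail(100, 10, 6, 3),
    tolerance = 1e-12
  )
})

test_that("hypergeometric tail equals exhaustive summation on a grid", {
  set.seed(2)
  for (i in 1:200) {
    N <- sample(2:60, 1)
    m <- sample(0:N, 1)
    k <- sample(1:N, 1)
    l <- sample(0:k, 1)
    got <- hypergeom_tail(N, m, k, l)
    want <- oracle_hyper_tail(N, m, k, l)
    expect_equal(got, want, tolerance = 1e-12,
                 label = sprintf("tail(N=%d,m=%d,k=%d,l=%d)", N, m, k, l))
  }
})

test_that("tail is monotone in l, m and k and normalises", {
  N <- 80
  # non-increasing in l
  t_l <- hypergeom_tail(N, 12, 10, 0:10)
  expect_false(is.unsorted(rev(t_l)))
  # non-decreasing in m
  t_m <- hypergeom_tail(N, 0:N, 10, 3)
  expect_false(is.unsorted(t_m))
  # non-decreasing in k
  t_k <- hypergeom_tail(N, 12, 3:N, 3)
  expect_false(is.unsorted(t_k))
  # point masses recovered from successive tails sum to 1
  tails <- hypergeom_tail(N, 12, 10, 0:10)
  masses <- tails - c(tails[-1], 0)
  expect_equal(sum(masses), 1, tolerance = 1e-12)
  expect_equal(tails[1], 1)
})

test_that("invalid tail parameters are rejected by name", {
  expect_error(hypergeom_tail(10, 11, 3, 1), "m <= N")
  expect_error(hypergeom_tail(10, 3, 11, 1), "l <= k <= N")
  expect_error(hypergeom_tail(10, 3, 3, -1), "l <= k")
})

test_that("chain scoring takes the most conservative term and e = p * N", {
  idx <- mk_index(100)
  # both terms are common to the whole chain; the more frequent one gives
  # the larger (more conservative) tail and must be the one reported.
  # remaining "common" carriers sit > max_gap apart so no other chain forms
  ann <- dplyr::bind_rows(
    mk_ann(sprintf("g%03d", 1:4), "rare"),
    mk_ann(sprintf("g%03d", c(1:4, 30, 50, 70, 90)), "common")
  )
  ch <- detect_chains(idx, ann)
  chain <- ch[ch$l == 4, ][1, ]
  expect_setequal(chain$common_terms[[1]], c("rare", "common"))
  sc <- score_chains(chain, ann, idx)
  expect_equal(sc$term_used, "common")
  expect_equal(sc$m_used, 8L)
  expect_equal(sc$p_value, hypergeom_tail(100, 8, sc$k, 4))
  expect_equal(sc$e_value, sc$p_value * 100)
})

test_that("scoring a tiny all-member genome gives the trivial tail", {
  idx <- mk_index(4)
  ann <- mk_ann(idx$gene_id, "A")
  sc <- score_chains(detect_chains(idx, ann), ann, idx)
  expect_equal(sc$l, 4L)
  expect_equal(sc$p_value, 1) # l = k = N, m = N
  expect_equal(sc$e_value, 4)
})

test_that("scoring rejects terms missing from the frequency table", {
  idx <- mk_index(6)
  ann <- mk_ann(c("g001", "g002"), "A")
  ch <- detect_chains(idx, ann)
  expect_error(score_chains(ch, mk_ann("g001", "B"), idx), "missing from")
})

test_that("filtering applies a strict expectation threshold", {
  idx <- mk_index(6)
  ann <- mk_ann(c("g001", "g002"), "A")
  sc <- score_chains(detect_chains(idx, ann), ann, idx)
  expect_equal(nrow(filter_significant(sc, sc$e_value[1] + 1e-9)), 1L)
  expect_equal(nrow(filter_significant(sc, sc$e_value[1])), 0L)
  expect_equal(nrow(filter_significant(sc[0, ], 0.01)), 0L)
  expect_error(filter_significant(detect_chains(idx, ann)), "scored")
})

test_that("significant sets are nested across ascending thresholds", {
  sim <- simulate_genome(tiny_sim_config(seed = 9))
  idx <- build_gene_index(sim$genes)
  sc <- score_chains(detect_chains(idx, sim$annotations), sim$annotations, idx)
  prev <- character(0)
  for (t in c(0.01, 0.05, 0.1, 0.15)) {
    ids <- filter_significant(sc, t)$chain_id
    expect_true(all(prev %in% ids))
    prev <- ids
  }
})
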