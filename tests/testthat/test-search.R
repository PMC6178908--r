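test_that("complete-linkage initialization honours trivial and grouped cuts", {
  aln <- make_aln(c(strrep("a", 8), strrep("a", 8), strrep("a", 8),
                    strrep("t", 8), strrep("t", 8), strrep("t", 8)))
  snp <- encode_snp_matrix(aln)
  n <- 6
  expect_identical(initialize_partition(snp, 1), rep(1L, n))
  # two groups of identical sequences: the cut recovers the groups, and
  # identical sequences can never be forced apart
  expect_identical(initialize_partition(snp, 2), rep(c(1L, 2L), each = 3))
  expect_identical(initialize_partition(snp, n), rep(c(1L, 2L), each = 3))
  expect_error(initialize_partition(snp, 0), class = "hb_bad_argument")

  # distinct sequences, k_init = n: every sequence its own cluster
  snp2 <- make_random_snp(5, 30, seed = 3, miss = 0)
  expect_identical(sort(unique(initialize_partition(snp2, 5))), 1:5)
})

test_that("reassignment sweep fixes a planted mislabeling and merges twins", {
  set.seed(1)
  # two well-separated planted clusters, one sequence mislabeled
  sim <- simulate_alignment(c(6, 6), n_loci = 80, seed = 12)
  snp <- encode_snp_matrix(new_alignment(sim$ids, sim$sequences))
  truth <- sim$labels$level1
  bad <- truth
  bad[1] <- 2
  state <- sweep_reassign_individuals(new_search_state(snp, bad, k_max = 2))
  expect_identical(compact_labels(state$labels), compact_labels(truth))
  # direct evaluation confirms the corrected labelling scores higher
  expect_gt(partition_log_ml(snp, truth), partition_log_ml(snp, bad))

  # n identical sequences collapse to one cluster from any start
  alnid <- make_aln(rep(strrep("at", 10), 6))
  snpid <- encode_snp_matrix(make_aln(c(rep(strrep("a", 6), 3),
                                        rep(strrep("t", 6), 3))))
  sub <- subset_snp_matrix(snpid, 1:3)  # identical triple, zero loci left
  expect_identical(ncol(sub$codes), 0L)
  # same property through the likelihood: on exchangeable identical data a
  # reassignment sweep started from K = 3 ends at K = 1
  snp3 <- encode_snp_matrix(make_aln(c("aattaa", "aattaa", "aattaa",
                                       "ttaatt", "ttaatt", "ttaatt")))
  st <- sweep_reassign_individuals(
    new_search_state(snp3, c(1, 2, 3, 1, 2, 3), k_max = 3))
  final <- sweep_merge_clusters(st)
  expect_identical(final$K, 2L)
  expect_identical(compact_labels(final$labels), rep(c(1L, 2L), each = 3))
})

test_that("sweeps leave an exhaustive-oracle optimum untouched", {
  snp <- make_random_snp(6, 12, seed = 21)
  opt <- oracle_map(snp, k_max = 3)
  state <- new_search_state(snp, opt$labels, k_max = 3)
  set.seed(5)
  s1 <- sweep_reassign_individuals(state)
  expect_identical(s1$labels, state$labels)
  s2 <- sweep_merge_clusters(state)
  expect_equal(s2$log_ml, state$log_ml, tolerance = 1e-12)
  s3 <- sweep_split_relocate(state)
  expect_identical(s3$labels, state$labels)
})

test_that("merge sweep joins duplicated clusters and respects separation", {
  # two clusters holding copies of the same sequence get merged
  snp <- encode_snp_matrix(make_aln(c("aat", "aat", "aat", "tta", "tta", "tta")),
                           keep_singletons = TRUE)
  st <- sweep_merge_clusters(new_search_state(snp, c(1, 2, 2, 3, 3, 3),
                                              k_max = 4))
  expect_identical(st$K, 2L)
  # planted well-separated clusters survive a merge sweep
  sim <- simulate_alignment(c(8, 8), n_loci = 100, seed = 30)
  snp2 <- encode_snp_matrix(new_alignment(sim$ids, sim$sequences))
  st2 <- new_search_state(snp2, sim$labels$level1, k_max = 4)
  expect_identical(sweep_merge_clusters(st2)$K, 2L)
  # K = 1 is a no-op
  st1 <- new_search_state(snp2, rep(1, 16), k_max = 4)
  expect_identical(sweep_merge_clusters(st1)$labels, st1$labels)
})

test_that("subgroup relocation splits a cluster hiding two subpopulations", {
  sim <- simulate_alignment(c(8, 8), n_loci = 100, seed = 44)
  snp <- encode_snp_matrix(new_alignment(sim$ids, sim$sequences))
  state <- new_search_state(snp, rep(1, 16), k_max = 3)
  set.seed(2)
  out <- sweep_split_relocate(state)
  expect_gt(out$K, 1L)
  expect_gt(out$log_ml, state$log_ml)
  expect_equal(adjusted_rand_index(out$labels, sim$labels$level1), 1)
  # clusters smaller than four members are never candidates
  small <- new_search_state(snp, rep(1:6, length.out = 16)[1:16], k_max = 6)
  sizes_ok <- all(small$sizes <= 3)
  if (sizes_ok) expect_identical(sweep_split_relocate(small)$labels,
                                 small$labels)
})

test_that("greedy search recovers the planted MAP and is deterministic", {
  # two groups of identical triples: exhaustive enumeration says the MAP
  # is the 2-cluster grouping
  snp <- encode_snp_matrix(make_aln(c(rep("aattaaggcc", 3),
                                      rep("ttaattccgg", 3))))
  opt <- oracle_map(snp, k_max = 3)
  expect_identical(opt$labels, rep(c(1L, 2L), each = 3))
  gs <- greedy_search(snp, 3, seed = 9)
  expect_identical(gs$labels, opt$labels)
  expect_equal(gs$log_ml, opt$log_ml, tolerance = 1e-9)
  expect_equal(gs$log_ml, partition_log_ml(snp, gs$labels), tolerance = 1e-9)

  # k_max = 1: the single-cluster partition, no search
  g1 <- greedy_search(snp, 1, seed = 9)
  expect_identical(g1$labels, rep(1L, 6))

  # identical inputs and seed give identical outputs, twice over
  snp2 <- make_random_snp(12, 30, seed = 8)
  a <- greedy_search(snp2, 4, seed = 123, n_restarts = 3)
  b <- greedy_search(snp2, 4, seed = 123, n_restarts = 3)
  expect_identical(a, b)
  c2 <- greedy_search(snp2, 4, seed = 124, n_restarts = 3)
  expect_true(is.integer(c2$labels))
})

test_that("the cached log-ML is non-decreasing over every sweep", {
  snp <- make_random_snp(15, 40, seed = 55)
  gs <- greedy_search(snp, 5, seed = 77, n_restarts = 2, trace = TRUE)
  expect_true(all(diff(gs$trace) >= -1e-9))
  expect_gte(length(gs$trace), 4L)
})

test_that("worker count does not change search results", {
  snp <- make_random_snp(14, 30, seed = 66)
  serial <- greedy_search(snp, 4, seed = 5, n_restarts = 3, workers = 1)
  forked <- greedy_search(snp, 4, seed = 5, n_restarts = 3, workers = 2)
  expect_identical(serial, forked)
})
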