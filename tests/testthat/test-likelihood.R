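test_that("single-cluster single-locus marginal matches hand-derived values", {
  # empty cluster: every gamma ratio collapses
  expect_identical(cluster_locus_log_ml(c(0, 0), 0.5), 0)
  # counts (1,1), alpha 1/2: Gamma(1)/Gamma(3) * (Gamma(1.5)/Gamma(0.5))^2
  expect_equal(cluster_locus_log_ml(c(1, 1), 0.5), log(0.125), tolerance = 1e-12)
  # counts (2,0): homogeneous counts score higher than split counts
  expect_equal(cluster_locus_log_ml(c(2, 0), 0.5), log(0.375), tolerance = 1e-12)
  expect_gt(cluster_locus_log_ml(c(2, 0), 0.5),
            cluster_locus_log_ml(c(1, 1), 0.5))

  expect_error(cluster_locus_log_ml(c(-1, 2), 0.5), class = "hb_bad_argument")
  expect_error(cluster_locus_log_ml(c(1, 2), 0), class = "hb_bad_argument")
})

test_that("closed form agrees with the sequential-predictive oracle", {
  set.seed(31)
  for (i in 1:200) {
    A <- sample(2:4, 1)
    counts <- rpois(A, sample(1:20, 1))
    expect_equal(cluster_locus_log_ml(counts, 1 / A),
                 oracle_locus_lml(counts, 1 / A), tolerance = 1e-10)
  }
})

test_that("two-allele loci reduce to the beta-binomial marginal", {
  for (a in c(0.25, 0.5, 1)) {
    for (cnt in list(c(3, 5), c(10, 0), c(1, 7))) {
      expect_equal(cluster_locus_log_ml(cnt, a),
                   lbeta(a + cnt[1], a + cnt[2]) - lbeta(a, a),
                   tolerance = 1e-12)
    }
  }
})

test_that("partition log-ML is additive over clusters and label-symmetric", {
  snp <- make_random_snp(8, 25, seed = 11)
  labels <- c(1, 1, 2, 3, 2, 1, 3, 3)
  base <- partition_log_ml(snp, labels)
  expect_equal(base, oracle_partition_lml(snp, labels), tolerance = 1e-9)

  # label permutation leaves the value unchanged
  perm <- c(3, 1, 2)[labels]
  expect_equal(partition_log_ml(snp, perm), base, tolerance = 1e-12)

  # additivity: per-cluster terms computed in isolation sum to the total
  st <- new_search_state(snp, labels)
  expect_equal(sum(st$cluster_lml), base, tolerance = 1e-9)

  expect_error(partition_log_ml(snp, c(1, 2)),
               class = "hb_dimension_mismatch")
})

test_that("the true 2-group split is the exhaustive MAP on paired data", {
  # two identical pairs differing from each other at every locus
  aln <- make_aln(c(strrep("a", 10), strrep("a", 10),
                    strrep("t", 10), strrep("t", 10)))
  snp <- encode_snp_matrix(aln)
  truth <- c(1, 1, 2, 2)
  parts <- all_partitions(4)
  expect_length(parts, 15L)
  scores <- vapply(parts, function(p) partition_log_ml(snp, p), numeric(1))
  best <- parts[[which.max(scores)]]
  expect_identical(best, as.integer(truth))
  expect_gt(partition_log_ml(snp, truth), partition_log_ml(snp, rep(1, 4)))
})

test_that("the posterior shifts the likelihood by a constant prior", {
  snp <- make_random_snp(6, 15, seed = 2)
  la <- c(1, 1, 2, 2, 3, 3)
  lb <- c(1, 2, 3, 1, 2, 3)
  # equal K: posterior difference equals likelihood difference
  expect_equal(log_posterior(snp, la, k_max = 3) -
                 log_posterior(snp, lb, k_max = 3),
               partition_log_ml(snp, la) - partition_log_ml(snp, lb),
               tolerance = 1e-12)
  # k_max = 1: posterior is the likelihood up to a constant
  expect_equal(log_posterior(snp, rep(1, 6), k_max = 1),
               partition_log_ml(snp, rep(1, 6)), tolerance = 1e-12)
  # posterior argmax on the paired toy equals the likelihood argmax
  aln <- make_aln(c(strrep("a", 10), strrep("a", 10),
                    strrep("t", 10), strrep("t", 10)))
  snp4 <- encode_snp_matrix(aln)
  parts <- all_partitions(4)
  post <- vapply(parts, function(p) log_posterior(snp4, p, k_max = 4),
                 numeric(1))
  expect_identical(parts[[which.max(post)]], c(1L, 1L, 2L, 2L))

  expect_error(log_posterior(snp, la, k_max = 2), class = "hb_bad_argument")
})

test_that("incremental deltas equal from-scratch recomputation", {
  snp <- make_random_snp(8, 20, seed = 17)
  set.seed(400)
  state <- new_search_state(snp, sample.int(3, 8, replace = TRUE), k_max = 4)
  for (rep in 1:50) {
    s <- sample.int(8, 1)
    from <- state$labels[s]
    cand <- setdiff(seq_len(state$K + as.integer(state$K < state$k_max)), from)
    to <- cand[sample.int(length(cand), 1)]
    d <- delta_log_ml_move(state, s, from, to)
    before <- partition_log_ml(snp, state$labels)
    state <- apply_move(state, s, to)
    expect_equal(as.numeric(d),
                 partition_log_ml(snp, state$labels) - before,
                 tolerance = 1e-9)
    expect_equal(state$log_ml, partition_log_ml(snp, state$labels),
                 tolerance = 1e-9)
  }
})

test_that("inverse moves cancel and twin-joining moves never hurt", {
  aln <- make_aln(c("aaaaa", "aaaaa", "ttttt", "ttttt", "tttta"))
  snp <- encode_snp_matrix(aln, keep_singletons = TRUE)
  state <- new_search_state(snp, c(1, 2, 3, 3, 3), k_max = 5)
  # move a sequence to a new cluster and back: net delta zero
  d_out <- delta_log_ml_move(state, 3, 3, 4)
  state2 <- apply_move(state, 3, 4)
  d_back <- delta_log_ml_move(state2, 3, 4, 3)
  expect_equal(as.numeric(d_out) + as.numeric(d_back), 0, tolerance = 1e-10)
  # moving a sequence into the cluster holding its twin is never negative
  d_twin <- delta_log_ml_move(state, 1, 1, 2)
  expect_gte(as.numeric(d_twin), 0)
  # the delta reports when the source cluster would empty
  expect_true(attr(delta_log_ml_move(state, 1, 1, 2), "empties_from"))
  expect_false(attr(delta_log_ml_move(state, 3, 3, 2), "empties_from"))

  expect_error(delta_log_ml_move(state, 1, 2, 3), class = "hb_invalid_move")
  expect_error(delta_log_ml_move(state, 1, 1, 1), class = "hb_invalid_move")
})
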