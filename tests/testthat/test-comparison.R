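part_df <- function(labels, ids = sprintf("n%d", seq_along(labels))) {
  tibble::tibble(concept_id = ids, community = labels)
}

test_that("ARI matches hand-derived reference values", {
  expect_equal(adjusted_rand_index(part_df(c(1, 1, 1, 2, 2, 2)),
                                   part_df(c(1, 1, 1, 2, 2, 2))), 1)
  # one side all singletons: no agreement beyond chance
  expect_equal(adjusted_rand_index(part_df(c(1, 1, 1, 2, 2, 2)),
                                   part_df(1:6)), 0)
  # maximally crossed 2x2 design: both the pair-counting oracle and the
  # contingency formula give -1/2
  expect_equal(adjusted_rand_index(part_df(c(1, 1, 2, 2)),
                                   part_df(c(1, 2, 1, 2))), -0.5)
  expect_equal(ari_pair_oracle(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  expect_error(adjusted_rand_index(part_df(c(1, 2)),
                                   part_df(c(1, 2), ids = c("a", "b"))),
               "different node sets")
  expect_error(adjusted_rand_index(part_df(1), part_df(1)), "at least 2")
})

test_that("AMI matches its defining properties", {
  expect_equal(adjusted_mutual_information(part_df(c(1, 2, 1, 2)),
                                           part_df(c(2, 1, 2, 1))), 1)
  # zero-entropy partition vs anything non-identical: exactly 0
  expect_equal(adjusted_mutual_information(part_df(c(1, 1, 1, 1)),
                                           part_df(c(1, 1, 2, 2))), 0)
  # crossed case agrees with the exhaustive permutation-model oracle
  x <- c(1, 1, 2, 2)
  y <- c(1, 2, 1, 2)
  expect_equal(adjusted_mutual_information(part_df(x), part_df(y)),
               ami_oracle(x, y), tolerance = 1e-12)
})

test_that("ARI and AMI agree with independent oracles over random partitions", {
  set.seed(91)
  for (rep in 1:25) {
    n <- sample(4:8, 1)
    x <- sample(1:3, n, replace = TRUE)
    y <- sample(1:3, n, replace = TRUE)
    expect_equal(adjusted_rand_index(part_df(x), part_df(y)),
                 ari_pair_oracle(x, y), tolerance = 1e-12)
    if (n <= 6) {
      expect_equal(adjusted_mutual_information(part_df(x), part_df(y)),
                   ami_oracle(x, y), tolerance = 1e-12)
    }
    if (requireNamespace("mclust", quietly = TRUE)) {
      expect_equal(adjusted_rand_index(part_df(x), part_df(y)),
                   mclust::adjustedRandIndex(x, y), tolerance = 1e-12)
    }
  }
})

test_that("ARI and AMI are symmetric and label-permutation invariant", {
  set.seed(92)
  for (rep in 1:10) {
    x <- sample(1:3, 6, replace = TRUE)
    y <- sample(1:3, 6, replace = TRUE)
    relab <- sample(10:12)[x]
    expect_equal(adjusted_rand_index(part_df(x), part_df(y)),
                 adjusted_rand_index(part_df(y), part_df(x)))
    expect_equal(adjusted_rand_index(part_df(relab), part_df(y)),
                 adjusted_rand_index(part_df(x), part_df(y)))
    expect_equal(adjusted_mutual_information(part_df(x), part_df(y)),
                 adjusted_mutual_information(part_df(y), part_df(x)))
    expect_equal(adjusted_mutual_information(part_df(relab), part_df(y)),
                 adjusted_mutual_information(part_df(x), part_df(y)))
  }
})

test_that("partition-pair generator hits its similarity regimes", {
  pq <- partition_pair_with_ari(10, "identical", seed = 3)
  expect_equal(adjusted_rand_index(pq$p, pq$q), 1)
  expect_equal(adjusted_mutual_information(pq$p, pq$q), 1)

  pq <- partition_pair_with_ari(8, "nested", seed = 3)
  expect_equal(adjusted_rand_index(pq$p, pq$q),
               ari_pair_oracle(pq$p$community, pq$q$community))

  aris <- vapply(1:200, function(s) {
    pq <- partition_pair_with_ari(12, "independent", seed = s)
    adjusted_rand_index(pq$p, pq$q)
  }, numeric(1))
  se <- stats::sd(aris) / sqrt(length(aris))
  expect_lt(abs(mean(aris)), 3 * se + 1e-9)
})

test_that("pairwise family similarity restricts to shared attested nodes", {
  ids <- sprintf("n%02d", 1:8)
  sims <- simulate_family_networks(ids, n_families = 2, n_blocks = 2,
                                   p_in = 1, p_out = 0, shared = TRUE,
                                   seed = 8)
  parts <- lapply(sims$nets, walk_partition)
  out <- pairwise_family_similarity(parts, domain = "body")
  expect_equal(nrow(out), 1)
  expect_equal(out$ari, 1)
  expect_equal(out$ami, 1)

  # families sharing too few attested nodes are skipped
  empty_net <- new_colex_network(
    tibble::tibble(concept_id = ids),
    tibble::tibble(concept_a = "n01", concept_b = "n02",
                   variety_count = 1L, family_count = 1L,
                   cognate_set_count = 1L)
  )
  parts2 <- list(A = parts[[1]], B = walk_partition(empty_net))
  out2 <- pairwise_family_similarity(parts2, domain = "body",
                                     min_shared = 3)
  expect_equal(nrow(out2), 0)
  expect_error(pairwise_family_similarity(parts[1]), "at least 2")
})

test_that("Welch t-test matches the closed form and is antisymmetric", {
  res <- welch_t_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$t, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(res$df, 4, tolerance = 1e-12)
  rev <- welch_t_test(c(4, 5, 6), c(1, 2, 3))
  expect_equal(rev$t, -res$t)
  expect_equal(rev$p_value, res$p_value)

  same <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)

  expect_error(welch_t_test(c(1, 1), c(1, 2)), "degenerate")
  expect_error(welch_t_test(1, c(1, 2)), "at least 2")
})

test_that("degree resampling matches its closed-form expectation", {
  # single edge of weight w in a pool of m nodes, sampling k:
  # E[summed degree] = 2 w k / m
  ids <- sprintf("n%02d", 1:10)
  net <- new_colex_network(
    tibble::tibble(concept_id = ids),
    tibble::tibble(concept_a = "n01", concept_b = "n02",
                   variety_count = 1L, family_count = 1L,
                   cognate_set_count = 1L, weight = 3),
    weight_field = "weight", n_varieties = 1L
  )
  trials <- degree_resampling(list(dom = list(famA = net)),
                              list(dom = ids), n = 4, trials = 1000,
                              seed = 10)
  expect_equal(nrow(trials), 1000)
  expected <- 2 * 3 * 4 / 10
  se <- stats::sd(trials$weighted_degree) / sqrt(1000)
  expect_lt(abs(mean(trials$weighted_degree) - expected), 3 * se)

  # sampling the whole pool leaves nothing to chance
  full <- degree_resampling(list(dom = list(famA = net)), list(dom = ids),
                            trials = 5, seed = 1)
  expect_equal(stats::sd(full$weighted_degree), 0)
  expect_equal(full$weighted_degree[1], 6)

  # an edgeless family scores zero in every trial
  empty <- new_colex_network(
    tibble::tibble(concept_id = ids),
    tibble::tibble(concept_a = character(0), concept_b = character(0),
                   variety_count = integer(0), family_count = integer(0),
                   cognate_set_count = integer(0)),
    n_varieties = 2L
  )
  z <- degree_resampling(list(dom = list(famA = empty)), list(dom = ids),
                         n = 5, trials = 10, seed = 2)
  expect_true(all(z$weighted_degree == 0))

  expect_error(degree_resampling(list(dom = list(famA = net)),
                                 list(dom = ids), trials = 0, seed = 1),
               "trials")
  expect_error(degree_resampling(list(dom = list(famA = net)),
                                 list(dom = ids), n = 11, trials = 1,
                                 seed = 1),
               "exceeds pool")
})

test_that("degree resampling depends only on the seed", {
  ids <- sprintf("n%02d", 1:8)
  sims <- simulate_family_networks(ids, n_families = 3, seed = 44)
  nets <- sims$nets
  a <- degree_resampling(list(d = nets), list(d = ids), n = 4, trials = 50,
                         seed = 123)
  b <- degree_resampling(list(d = rev(nets)), list(d = rev(ids)), n = 4,
                         trials = 50, seed = 123)
  expect_equal(as.data.frame(a), as.data.frame(b))
  c2 <- degree_resampling(list(d = nets), list(d = ids), n = 4, trials = 50,
                          seed = 124)
  expect_false(isTRUE(all.equal(a$weighted_degree, c2$weighted_degree)))
})

test_that("normalisation divides by the family's variety count", {
  ids <- sprintf("n%02d", 1:4)
  net <- new_colex_network(
    tibble::tibble(concept_id = ids),
    tibble::tibble(concept_a = "n01", concept_b = "n02",
                   variety_count = 10L, family_count = 1L,
                   cognate_set_count = 1L),
    weight_field = "varieties", n_varieties = 5L
  )
  full <- degree_resampling(list(d = list(f = net)), list(d = ids),
                            trials = 1, seed = 1)
  expect_equal(full$weighted_degree, 2 * 10 / 5)
})
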