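test_that("z-spectrum matches independent high-precision evaluation", {
  grid <- expand.grid(C1 = c(0.05, 0.3, 0.5, 0.9, 0.999),
                      C2 = c(0, 0.1, 0.45, 0.8),
                      d1 = c(12, 270, 1080), d2 = c(30, 1080))
  for (i in seq_len(nrow(grid))) {
    z <- z_difference(as_coherence(0, grid$C1[i], d = grid$d1[i]),
                      as_coherence(0, grid$C2[i], d = grid$d2[i]))
    oracle <- z_oracle(grid$C1[i], grid$C2[i], grid$d1[i], grid$d2[i])
    expect_equal(z$z, oracle, tolerance = 1e-12)
  }
  # the worked value: C1 = 0.5, C2 = 0.3, d1 = d2 = 1080
  z <- z_difference(as_coherence(0:1, c(0.5, 0.5), d = 1080),
                    as_coherence(0:1, c(0.3, 0.3), d = 1080))
  expect_equal(z$z, rep((atanh(0.5) - atanh(0.3)) / sqrt(2 / 1078), 2),
               tolerance = 1e-12)
})

test_that("z-difference is antisymmetric and vanishes for identical inputs", {
  set.seed(3)
  C <- stats::runif(40, 0, 0.9)
  a <- as_coherence(0:39, C, d = 540)
  b <- as_coherence(0:39, stats::runif(40, 0, 0.9), d = 540)
  expect_identical(z_difference(a, a)$z, rep(0, 40))
  expect_identical(z_difference(a, b)$z, -z_difference(b, a)$z)
})

test_that("z-difference validates dofs and grids", {
  a <- as_coherence(0:10, rep(0.4, 11), d = 100)
  b <- as_coherence(0:10, rep(0.3, 11), d = 2)
  expect_error(z_difference(a, b), "dof error")
  c2 <- as_coherence(seq(0, 20, 2), rep(0.3, 11), d = 100)
  expect_error(z_difference(a, c2), "pairing error")
  # C = 1 survives via clipping
  d1 <- as_coherence(0:10, rep(1, 11), d = 100)
  expect_true(all(is.finite(z_difference(d1, a)$z)))
})

test_that("cluster extraction follows strict-threshold adjacency", {
  z <- structure(tibble::tibble(freq = 15:19, z = c(0, 3, 3, 0, 3)),
                 class = c("cmc_zspectrum", class(tibble::tibble())))
  cl <- find_clusters(z, threshold = 2, band = c(15, 19))
  expect_identical(nrow(cl), 2L)
  expect_equal(cl$mass, c(6, 3))
  expect_equal(cl$start_freq, c(16, 19))
  expect_equal(cl$end_freq, c(17, 19))
  expect_equal(max_cluster_stat(cl), 6)

  below <- structure(tibble::tibble(freq = 15:19, z = rep(1, 5)),
                     class = class(z))
  expect_identical(nrow(find_clusters(below, 2, c(15, 19))), 0L)
  expect_identical(max_cluster_stat(find_clusters(below, 2, c(15, 19))), 0)

  ties <- structure(tibble::tibble(freq = 15:19, z = rep(2, 5)),
                    class = class(z))
  expect_identical(nrow(find_clusters(ties, 2, c(15, 19))), 0L)

  expect_error(find_clusters(z, 2, c(40, 50)), "band error")
  expect_error(find_clusters(z, -1, c(15, 19)), "threshold")
})

test_that("two-sided clustering splits excursions by sign", {
  z <- structure(tibble::tibble(freq = 15:20, z = c(3, 3, -4, -4, 0, 3)),
                 class = c("cmc_zspectrum", class(tibble::tibble())))
  cl <- find_clusters(z, 2, c(15, 20), alternative = "two.sided")
  expect_identical(nrow(cl), 3L)
  expect_equal(cl$mass, c(6, 8, 3))
  expect_identical(cl$sign, c(1L, -1L, 1L))
  expect_equal(max_cluster_stat(cl), 8)
})

test_that("random partitions conserve the pooled epochs and are seeded", {
  set.seed(10)
  d1 <- array(stats::rnorm(2 * 16 * 4), dim = c(2, 16, 4))
  d2 <- array(stats::rnorm(2 * 16 * 3), dim = c(2, 16, 3))
  ep1 <- manual_epochs(d1, fs = 16)
  ep2 <- manual_epochs(d2, fs = 16)

  set.seed(1)
  pr <- random_partition(ep1, ep2)
  expect_identical(dim(pr[[1]]$data)[3], 4L)
  expect_identical(dim(pr[[2]]$data)[3], 3L)
  pooled_in <- cbind(matrix(d1, 32), matrix(d2, 32))
  pooled_out <- cbind(matrix(pr[[1]]$data, 32), matrix(pr[[2]]$data, 32))
  expect_identical(sort(pooled_in[1, ]), sort(pooled_out[1, ]))

  set.seed(42)
  a <- random_partition(ep1, ep2)
  set.seed(42)
  b <- random_partition(ep1, ep2)
  expect_identical(a[[1]]$data, b[[1]]$data)
})

test_that("partitions of (2, 2) epochs are uniform over the 6 assignments", {
  d1 <- array(seq_len(2 * 8 * 2), dim = c(2, 8, 2))
  d2 <- array(100 + seq_len(2 * 8 * 2), dim = c(2, 8, 2))
  ep1 <- manual_epochs(d1, fs = 8)
  ep2 <- manual_epochs(d2, fs = 8)
  set.seed(123)
  keys <- replicate(1000, {
    pr <- random_partition(ep1, ep2)
    paste(sort(pr[[1]]$data[1, 1, ]), collapse = "_")
  })
  freq <- table(keys) / 1000
  expect_identical(length(freq), 6L)   # exhaustive enumeration: 4!/(2!2!)
  expect_true(all(abs(freq - 1 / 6) < 0.05))
})

test_that("permutation test implements the add-one Monte Carlo rule", {
  s1 <- tiny_session(seed = 101, n_trials = 4, coupling_gain = 0.05)
  s2 <- tiny_session(seed = 102, n_trials = 4, coupling_gain = 2.5)
  ep1 <- segment_epochs(s1$recording)
  ep2 <- segment_epochs(s2$recording)
  tgt <- s1$truth$target_electrode
  res <- permutation_test(ep2, ep1, eeg = tgt, n_perm = 200, seed = 9)
  expect_identical(length(res$null_stats), 200L)
  expect_equal(res$p_mc,
               (1 + sum(res$null_stats >= res$observed_stat)) / 201)
  expect_gt(res$observed_stat, 0)
  if (res$observed_stat > max(res$null_stats)) {
    expect_equal(res$p_mc, 1 / 201)
  }
  expect_lt(res$p_mc, 0.05)

  gl <- glance(res)
  expect_identical(gl$p_mc, res$p_mc)
  td <- tidy(res)
  expect_true(all(td$mass > 0))
  expect_equal(max_cluster_stat(res$clusters), res$observed_stat)
})

test_that("the observed statistic ignores epoch order within conditions", {
  s1 <- tiny_session(seed = 103, n_trials = 4, coupling_gain = 0.4)
  s2 <- tiny_session(seed = 104, n_trials = 4, coupling_gain = 1.4)
  ep1 <- segment_epochs(s1$recording)
  ep2 <- segment_epochs(s2$recording)
  tgt <- s1$truth$target_electrode
  r1 <- permutation_test(ep2, ep1, eeg = tgt, n_perm = 120, seed = 1)
  L <- dim(ep2$data)[3]
  set.seed(77)
  shuf <- cmcoh:::subset_epochs(ep2, sample(L))
  r2 <- permutation_test(shuf, ep1, eeg = tgt, n_perm = 120, seed = 1)
  expect_equal(r1$observed_stat, r2$observed_stat, tolerance = 1e-12)
})

test_that("small n_perm warns and empty epoch sets error", {
  s1 <- tiny_session(seed = 105, n_trials = 3)
  ep1 <- segment_epochs(s1$recording)
  expect_warning(permutation_test(ep1, ep1, eeg = "E001", n_perm = 50,
                                  seed = 2),
                 "coarse")
})
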