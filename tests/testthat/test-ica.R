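test_that("full-rank decomposition reconstructs the input and is seeded", {
  sim <- tiny_session(seed = 91, n_trials = 2, montage_size = 8)
  rec <- sim$recording
  ica <- suppressMessages(fit_ica(rec, seed = 5, max_iter = 50))
  recon <- ica$mixing %*% ica$sources + ica$center
  rel <- max(abs(recon - rec$data[ica$eeg_idx, ])) /
    max(abs(rec$data[ica$eeg_idx, ]))
  expect_lt(rel, 1e-6)
  expect_lt(max(abs(ica$unmixing %*% ica$mixing - diag(ica$n_components))),
            1e-6)

  ica2 <- suppressMessages(fit_ica(rec, seed = 5, max_iter = 50))
  expect_identical(ica$unmixing, ica2$unmixing)
  expect_identical(ica$sources, ica2$sources)
})

test_that("rank-deficient data triggers a rank error advising reduction", {
  sim <- tiny_session(seed = 92, n_trials = 2, montage_size = 8)
  rec <- sim$recording
  rec$data[3, ] <- rec$data[2, ]   # exact copy of a channel
  expect_error(fit_ica(rec), "rank error")
  expect_error(fit_ica(rec), "n_components")
})

test_that("too-short recordings are rejected", {
  rec <- new_recording(matrix(stats::rnorm(8 * 100), 8), fs = 100,
                       labels = sprintf("E%03d", 1:8))
  expect_error(fit_ica(rec), "20 samples per channel")
})

test_that("injected 50-Hz interference is scored and removed cleanly", {
  p <- sim_params(montage_size = 32, n_trials = 6, n_runs = 1, seed = 93,
                  artifacts = list(blink = FALSE, ecg = FALSE, line50 = TRUE))
  sim <- simulate_session(p)
  rec <- sim$recording
  ica <- suppressMessages(fit_ica(rec, seed = 2, max_iter = 50))
  sc <- score_artifacts(ica, rec)
  expect_true(all(sc$line >= 0 & sc$line <= 1))
  expect_gt(max(sc$line), 0.8)
  expect_lt(sort(sc$line, decreasing = TRUE)[2], 0.1)

  bad <- sc$component[sc$line > 0.7]
  cleaned <- remove_components(rec, ica, bad)
  eeg <- ica$eeg_idx
  line0 <- sum(vapply(eeg, function(c) band_power(rec$data[c, ], 1000, 49.5, 50.5), 0))
  line1 <- sum(vapply(eeg, function(c) band_power(cleaned$data[c, ], 1000, 49.5, 50.5), 0))
  beta0 <- sum(vapply(eeg, function(c) band_power(rec$data[c, ], 1000, 15, 30), 0))
  beta1 <- sum(vapply(eeg, function(c) band_power(cleaned$data[c, ], 1000, 15, 30), 0))
  expect_gte(1 - line1 / line0, 0.9)
  expect_lt(abs(beta1 / beta0 - 1), 0.1)
})

test_that("blink and cardiac components score high only when present", {
  p <- sim_params(montage_size = 16, n_trials = 6, n_runs = 1, seed = 94,
                  artifacts = list(blink = TRUE, ecg = TRUE, line50 = FALSE))
  rec <- simulate_session(p)$recording
  ica <- suppressMessages(fit_ica(rec, seed = 2, max_iter = 50))
  sc <- score_artifacts(ica, rec)
  expect_gt(max(sc$blink), 0.7)
  expect_gt(max(sc$ecg), 0.7)

  clean <- tiny_session(seed = 95, n_trials = 6)$recording
  ica2 <- suppressMessages(fit_ica(clean, seed = 2, max_iter = 50))
  sc2 <- score_artifacts(ica2, clean)
  expect_true(all(sc2$blink < 0.7))
})

test_that("a constant-zero component scores zero on all three rules", {
  sim <- tiny_session(seed = 96, n_trials = 2, montage_size = 8)
  rec <- sim$recording
  ica <- suppressMessages(fit_ica(rec, seed = 1, max_iter = 30))
  ica$sources[2, ] <- 0
  sc <- score_artifacts(ica, rec)
  expect_identical(unlist(sc[2, c("blink", "ecg", "line")]),
                   c(blink = 0, ecg = 0, line = 0))
})

test_that("rejecting nothing is the identity; rejecting all is an error", {
  sim <- tiny_session(seed = 97, n_trials = 2, montage_size = 8)
  rec <- sim$recording
  ica <- suppressMessages(fit_ica(rec, seed = 1, max_iter = 30))
  same <- remove_components(rec, ica, integer())
  expect_identical(same$data, rec$data)
  expect_error(remove_components(rec, ica, seq_len(ica$n_components)),
               "degenerate-output")
  expect_error(remove_components(rec, ica, 99), "outside fitted")
})

test_that("automatic rejection leaves artifact-free data untouched", {
  rejected <- vapply(1:20, function(seed) {
    rec <- tiny_session(seed = seed, n_trials = 3, montage_size = 8)$recording
    out <- suppressMessages(clean_artifacts(rec, seed = 1))
    length(out$meta$ica_rejected)
  }, numeric(1))
  expect_gte(mean(rejected == 0), 0.95)
})
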