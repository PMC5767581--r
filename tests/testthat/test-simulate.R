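test_that("identical seeds give bit-identical sessions", {
  a <- tiny_session(seed = 11)
  b <- tiny_session(seed = 11)
  expect_identical(a$recording$data, b$recording$data)
  expect_identical(a$recording$events, b$recording$events)
  c <- tiny_session(seed = 12)
  expect_false(identical(a$recording$data, c$recording$data))
})

test_that("expected coherence obeys the closed-form limits", {
  p0 <- sim_params(coupling_gain = 0)
  expect_true(all(expected_coherence(p0)$coherence == 0))

  # noiseless single-peak limit: coherence 1 wherever the source has power
  p1 <- sim_params(eeg_noise_sd = 0, emg_noise_sd = 0, peak_freqs_hz = 21,
                   coupling_gain = 1)
  ec <- expected_coherence(p1)
  expect_equal(ec$coherence[ec$freq == 21], 1)
  expect_true(all(ec$coherence[ec$freq >= 18 & ec$freq <= 24] > 0.999))

  # monotone decreasing in noise wherever strictly between 0 and 1
  pa <- sim_params(coupling_gain = 1)
  pb <- sim_params(coupling_gain = 1, eeg_noise_sd = 2, emg_noise_sd = 2)
  ca <- expected_coherence(pa)$coherence
  cb <- expected_coherence(pb)$coherence
  mid <- ca > 0 & ca < 1
  expect_true(all(cb[mid] < ca[mid]))

  # monotone increasing in coupling gain at every frequency with power
  pk <- sim_params(coupling_gain = 2)
  ck <- expected_coherence(pk)$coherence
  expect_true(all(ck[mid] > ca[mid]))
})

test_that("decoupled sessions estimate coherence at the null level", {
  sim <- tiny_session(seed = 21, n_trials = 5, coupling_gain = 0)
  ep <- segment_epochs(sim$recording)
  co <- coherence_spectrum(ep, sim$truth$target_electrode, "EMG")
  # null mean of magnitude coherence ~ sqrt(pi / (4 K L)); stay well below
  # any genuine coupling level
  sel <- co$freq >= 15 & co$freq <= 30
  expect_lt(mean(co$coherence[sel]), 3 * sqrt(pi / (4 * attr(co, "d") / 2)))
})

test_that("degenerate parameter combinations are rejected", {
  expect_error(simulate_session(sim_params(coupling_gain = 0,
                                           emg_noise_sd = 0)),
               "degenerate-signal")
  expect_error(sim_params(peak_freqs_hz = 600), "peak frequencies")
  expect_error(sim_params(montage_size = 4), "at least 8")
  expect_error(sim_params(coupling_gain = -1), ">= 0")
})

test_that("force channel ramps to target, holds within bounds, rests at zero", {
  sim <- tiny_session(seed = 31)
  rec <- sim$recording
  force <- rec$data[rec$labels == "FORCE", ]
  fs <- rec$fs
  trials <- recording_trials(rec)
  expect_true(all(force >= 0 & force <= 3.5))
  for (i in seq_len(nrow(trials))) {
    hold <- (trials$start[i] + 2 * fs + 1):(trials$end[i])
    expect_equal(mean(force[hold]), 3, tolerance = 0.01)
  }
  gaps <- setdiff(seq_along(force) - 1,
                  unlist(lapply(seq_len(nrow(trials)),
                                function(i) trials$start[i]:(trials$end[i] - 1))))
  expect_true(all(force[gaps + 1] == 0))
})

test_that("session coupling defaults express recovery of the affected side", {
  expect_lt(
    max(expected_coherence(sim_params(side = "affected", session = 1))$coherence),
    max(expected_coherence(sim_params(side = "affected", session = 2))$coherence)
  )
  expect_identical(
    expected_coherence(sim_params(side = "unaffected", session = 1)),
    expected_coherence(sim_params(side = "unaffected", session = 2))
  )
})

test_that("mid-band estimate from 400 segments matches the closed form", {
  # oracle: large-sample empirical multitaper coherence from the simulator
  p <- sim_params(montage_size = 8, n_trials = 45, n_runs = 1, seed = 41)
  sim <- simulate_session(p)
  ep <- segment_epochs(sim$recording)
  ep <- cmcoh:::subset_epochs(ep, seq_len(400))
  tgt <- sim$truth$target_electrode
  co <- coherence_spectrum(ep, tgt, "EMG")
  truth <- sim$truth$expected

  for (f0 in c(19, 21, 23)) {
    est <- co$coherence[co$freq == f0]
    expected <- truth$coherence[truth$freq == f0]
    # jackknife-over-epochs standard error of the estimate at f0
    x <- epoch_channel(ep, tgt)
    y <- epoch_channel(ep, "EMG")
    tp <- make_tapers(nrow(x), 2, 3)
    X <- cmcoh:::tapered_dft_bins(x, tp, f0 + 1)
    Y <- cmcoh:::tapered_dft_bins(y, tp, f0 + 1)
    pxy <- drop(rowSums(X * Conj(Y), dims = 2))
    pxx <- drop(rowSums(Mod(X)^2, dims = 2))
    pyy <- drop(rowSums(Mod(Y)^2, dims = 2))
    L <- length(pxx)
    loo <- vapply(seq_len(L), function(l) {
      Mod(sum(pxy[-l])) / sqrt(sum(pxx[-l]) * sum(pyy[-l]))
    }, numeric(1))
    se <- sqrt((L - 1) / L * sum((loo - mean(loo))^2))
    expect_lt(abs(est - expected), 3 * se + 1e-12)
  }
})
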