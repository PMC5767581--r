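test_that("self-coherence and scale invariance are exact", {
  sim <- tiny_session(seed = 81, n_trials = 2, montage_size = 8)
  ep <- segment_epochs(sim$recording)
  tgt <- sim$truth$target_electrode
  self <- coherence_spectrum(ep, tgt, tgt)
  expect_lt(max(abs(self$coherence - 1)), 1e-9)

  scaled <- ep
  i <- match("EMG", ep$labels)
  scaled$data[i, , ] <- 3.7 * epoch_channel(ep, tgt)
  expect_lt(max(abs(coherence_spectrum(scaled, tgt, "EMG")$coherence - 1)),
            1e-9)

  co <- coherence_spectrum(ep, tgt, "EMG")
  expect_identical(attr(co, "d"), 2 * 3 * dim(ep$data)[3])
  expect_true(all(co$coherence >= 0 & co$coherence <= 1))
  expect_true(all(diff(co$freq) > 0))
})

test_that("multitaper estimator agrees with the brute-force DFT oracle", {
  set.seed(7)
  x <- matrix(stats::rnorm(64 * 8), 64, 8)
  y <- matrix(stats::rnorm(64 * 8), 64, 8)
  y[, 1:4] <- y[, 1:4] + 0.5 * x[, 1:4]
  # build a 2-channel epoch object directly
  data <- array(0, dim = c(2, 64, 8))
  data[1, , ] <- x
  data[2, , ] <- y
  ep <- manual_epochs(data, fs = 64)
  co <- coherence_spectrum(ep, "E001", "EMG", nw = 2, k = 3)
  oracle <- brute_coherence(x, y, make_tapers(64, 2, 3))
  expect_lt(max(abs(co$coherence - oracle)), 1e-12)
})

test_that("coherence is invariant to rescaling and epoch relabelling", {
  sim <- tiny_session(seed = 82, n_trials = 2, montage_size = 8)
  ep <- segment_epochs(sim$recording)
  tgt <- sim$truth$target_electrode
  base <- coherence_spectrum(ep, tgt, "EMG")

  resc <- ep
  resc$data[match(tgt, ep$labels), , ] <- 0.2 * resc$data[match(tgt, ep$labels), , ]
  resc$data[match("EMG", ep$labels), , ] <- 40 * resc$data[match("EMG", ep$labels), , ]
  expect_equal(coherence_spectrum(resc, tgt, "EMG")$coherence,
               base$coherence, tolerance = 1e-12)

  L <- dim(ep$data)[3]
  rot <- cmcoh:::subset_epochs(ep, c(2:L, 1))
  expect_equal(coherence_spectrum(rot, tgt, "EMG")$coherence,
               base$coherence, tolerance = 1e-12)
})

test_that("degenerate coherence inputs are rejected", {
  sim <- tiny_session(seed = 83, n_trials = 2, montage_size = 8)
  ep <- segment_epochs(sim$recording)
  dead <- ep
  dead$data[1, , ] <- 0
  expect_error(coherence_spectrum(dead, "E001", "EMG"), "degenerate-signal")
  short <- cmcoh:::subset_epochs(ep, 1:3)
  expect_error(coherence_spectrum(ep, "E001", "EMG", ep2 = short),
               "pairing error")
})

test_that("flat spectra give a flat topography with first-electrode tie-break", {
  freqs <- 0:50
  cohs <- lapply(1:5, function(i) as_coherence(freqs, rep(0.4, 51), d = 100))
  names(cohs) <- sprintf("E%03d", 1:5)
  topo <- band_topography(cohs, band = c(15, 30))
  expect_true(all(topo$coherence == 0.4))
  expect_identical(attr(topo, "peak_electrode"), "E001")
})

test_that("band limits are validated against the frequency grid", {
  sim <- tiny_session(seed = 84, n_trials = 2, montage_size = 8)
  ep <- segment_epochs(sim$recording)
  expect_silent(tp <- band_topography(ep, band = c(100, 200)))
  expect_true(all(tp$coherence >= 0))
  expect_error(band_topography(ep, band = c(600, 700)), "band error")
  expect_error(band_topography(ep, band = c(30, 15)), "band error")
})

test_that("topography recovers the simulated source at the target electrode", {
  sim <- tiny_session(seed = 85, n_trials = 5, montage_size = 16)
  ep <- segment_epochs(sim$recording)
  topo <- band_topography(ep)
  expect_identical(attr(topo, "peak_electrode"), sim$truth$target_electrode)
  expect_identical(topo$electrode[which.max(topo$coherence)],
                   attr(topo, "peak_electrode"))
})

test_that("spectral-domain CSD equals time-domain CSD in the topography", {
  sim <- tiny_session(seed = 86, n_trials = 2, montage_size = 16)
  ep <- segment_epochs(sim$recording)
  op <- csd_operator(sim$recording$meta$montage)
  slow <- band_topography(apply_csd(ep, op))
  fast <- band_topography(ep, csd = op)
  expect_equal(fast$coherence, slow$coherence, tolerance = 1e-10)
})

test_that("peak-spectrum selection is per session", {
  a <- segment_epochs(tiny_session(seed = 87, n_trials = 3, montage_size = 16)$recording,
                      condition = "s1")
  b <- segment_epochs(tiny_session(seed = 88, n_trials = 3, montage_size = 16)$recording,
                      condition = "s2")
  sel <- select_peak_spectrum(list(s1 = a, s2 = b))
  peaks <- attr(sel, "peaks")
  expect_identical(peaks$electrode[1], attr(band_topography(a), "peak_electrode"))
  expect_identical(peaks$electrode[2], attr(band_topography(b), "peak_electrode"))
  expect_identical(attr(sel$s1, "pair")[1], peaks$electrode[1])

  one <- select_peak_spectrum(list(only = a))
  expect_identical(attr(one, "peaks")$electrode,
                   attr(band_topography(a), "peak_electrode"))
})
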