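#' Simulation parameters for a coupled EEG/EMG/force session
#'
#' Builds the parameter set for [simulate_session()]. Defaults reproduce the
#' study conditions of a two-run elbow-flexion session: 11-s trials separated
#' by 2-s gaps, 20 trials per run, two runs, 128 scalp electrodes sampled at
#' 1000 Hz, a 3-N target force reached within the first 2 s of each trial.
#'
#' The generative model shares one band-limited cortical source between the
#' scalp and the muscle: the source spectrum is a sum of Gaussian lobes
#' centred at `peak_freqs_hz` (default 18 and 24 Hz, half-width
#' `source_bandwidth_hz` = 3 Hz, peak amplitude 1), EEG channel *i* receives
#' gain `exp(-spatial_decay * greatcircle(i, target))` plus white noise, and
#' the EMG receives the source delayed by `conduction_delay_ms` and scaled by
#' the coupling gain kappa, plus white noise, amplitude-modulated to be
#' near-zero outside contraction windows.
#'
#' If `coupling_gain` is `NULL` it is resolved from `side`/`session`:
#' 0.6 (affected, session 1), 1.2 (affected, session 2), 1.0 (unaffected) —
#' the affected side couples more strongly after recovery.
#'
#' @param fs Sampling rate, Hz.
#' @param n_trials Trials per run.
#' @param n_runs Runs per session.
#' @param trial_s,gap_s Trial length and inter-trial gap, seconds.
#' @param contraction_delay_s Time from trial start to stable target force.
#' @param montage_size Number of scalp electrodes (>= 8).
#' @param target_electrode Label where the spatial gain peaks; default the
#'   electrode nearest a left-central (motor-cortex-like) direction.
#' @param peak_freqs_hz Coupling peak frequencies, Hz (within the beta band).
#' @param coupling_gain Dimensionless EMG coupling amplitude kappa (>= 0).
#' @param source_bandwidth_hz Gaussian half-width of each spectral lobe, Hz.
#' @param eeg_noise_sd,emg_noise_sd White-noise SD, microvolts.
#' @param spatial_decay Gain fall-off rate per radian of great-circle
#'   distance from the target electrode.
#' @param artifacts Named logical flags `blink`, `ecg`, `line50`.
#' @param conduction_delay_ms Corticomuscular conduction delay, ms.
#' @param force_n Target force, newtons.
#' @param side `"affected"` or `"unaffected"`.
#' @param session Session number (1 or 2).
#' @param seed RNG seed; one stream drives the whole session.
#' @return A list of class `cmc_sim_params`.
#' @export
sim_params <- function(fs = 1000, n_trials = 20, n_runs = 2, trial_s = 11,
                       gap_s = 2, contraction_delay_s = 2, montage_size = 128,
                       target_electrode = NULL, peak_freqs_hz = c(18, 24),
                       coupling_gain = NULL, source_bandwidth_hz = 3,
                       eeg_noise_sd = 1, emg_noise_sd = 1, spatial_decay = 1.5,
                       artifacts = list(blink = FALSE, ecg = FALSE, line50 = FALSE),
                       conduction_delay_ms = 10, force_n = 3,
                       side = c("affected", "unaffected"), session = 1L,
                       seed = 1L) {
  side <- match.arg(side)
  p <- list(
    fs = fs, n_trials = n_trials, n_runs = n_runs, trial_s = trial_s,
    gap_s = gap_s, contraction_delay_s = contraction_delay_s,
    montage_size = montage_size, target_electrode = target_electrode,
    peak_freqs_hz = peak_freqs_hz, coupling_gain = coupling_gain,
    source_bandwidth_hz = source_bandwidth_hz, eeg_noise_sd = eeg_noise_sd,
    emg_noise_sd = emg_noise_sd, spatial_decay = spatial_decay,
    artifacts = artifacts, conduction_delay_ms = conduction_delay_ms,
    force_n = force_n, side = side, session = as.integer(session),
    seed = as.integer(seed)
  )
  class(p) <- "cmc_sim_params"
  validate_sim_params(p)
  p
}

validate_sim_params <- function(p) {
  pos <- c("fs", "n_trials", "n_runs", "trial_s", "gap_s",
           "contraction_delay_s", "source_bandwidth_hz", "force_n")
  for (nm in pos) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || p[[nm]] <= 0) {
      stop("simulation parameter error: '", nm, "' must be a positive scalar",
           call. = FALSE)
    }
  }
  if (!is.null(p$coupling_gain) && p$coupling_gain < 0) {
    stop("simulation parameter error: coupling gain must be >= 0", call. = FALSE)
  }
  if (any(p$peak_freqs_hz <= 0 | p$peak_freqs_hz >= p$fs / 2)) {
    stop("simulation parameter error: peak frequencies must lie in (0, fs/2)",
         call. = FALSE)
  }
  if (p$montage_size < 8) {
    stop("simulation parameter error: montage needs at least 8 electrodes",
         call. = FALSE)
  }
  if (p$contraction_delay_s >= p$trial_s) {
    stop("simulation parameter error: contraction delay exceeds trial length",
         call. = FALSE)
  }
  invisible(p)
}

resolve_coupling <- function(p) {
  if (!is.null(p$coupling_gain)) return(p$coupling_gain)
  if (p$side == "affected") c(0.6, 1.2)[p$session] else 1.0
}

sim_montage <- function(p) make_montage(p$montage_size)

resolve_target <- function(p, mont = sim_montage(p)) {
  if (!is.null(p$target_electrode)) {
    if (!p$target_electrode %in% mont$label) {
      stop("simulation parameter error: target electrode '",
           p$target_electrode, "' not in montage", call. = FALSE)
    }
    return(p$target_electrode)
  }
  # left-central direction, approximately over the hand motor area
  dir <- c(-0.6, 0, 0.8) / sqrt(1)
  dir <- dir / sqrt(sum(dir^2))
  pos <- montage_positions(mont)
  mont$label[which.max(pos %*% dir)]
}

# source amplitude spectrum: sum of Gaussian lobes, peak amplitude 1 each
source_amplitude <- function(p, freqs_hz) {
  A <- numeric(length(freqs_hz))
  for (fk in p$peak_freqs_hz) {
    A <- A + exp(-(freqs_hz - fk)^2 / (2 * p$source_bandwidth_hz^2))
  }
  A
}

#' Closed-form expected corticomuscular coherence
#'
#' For the linear mixing model `x = g*s + n_eeg`, `y = kappa*s + n_emg`
#' the magnitude coherence is
#' `C(f) = g*kappa*S_ss(f) / sqrt((g^2 S_ss + S_nn)(kappa^2 S_ss + S_mm))`.
#' With the simulator's unit-variance white noises and Gaussian source lobes
#' this evaluates per 1-Hz frequency bin as
#' `C(f) = g*kappa*A(f)^2 / sqrt((g^2 A^2 + sd_eeg^2)(kappa^2 A^2 + sd_emg^2))`.
#' A pure conduction delay leaves the magnitude unchanged.
#'
#' @param p A `cmc_sim_params`.
#' @param channel EEG electrode label; default the target electrode.
#' @return A tibble with columns `freq` (0 .. fs/2, 1-Hz grid) and
#'   `coherence` in `[0, 1]`.
#' @export
expected_coherence <- function(p, channel = NULL) {
  validate_sim_params(p)
  mont <- sim_montage(p)
  target <- resolve_target(p, mont)
  channel <- channel %||% target
  g <- exp(-p$spatial_decay * montage_distances(mont, target)[[channel]])
  kappa <- resolve_coupling(p)
  freqs <- seq(0, floor(p$fs / 2), by = 1)
  A2 <- source_amplitude(p, freqs)^2
  num <- g * kappa * A2
  den <- sqrt((g^2 * A2 + p$eeg_noise_sd^2) * (kappa^2 * A2 + p$emg_noise_sd^2))
  C <- ifelse(num == 0, 0, num / den)
  tibble::tibble(freq = freqs, coherence = pmin(1, C))
}

#' Simulate one session of coupled EEG/EMG/force recordings
#'
#' Generates a full session under the linear shared-source model described
#' in [sim_params()], with trial-event markers, a force channel ramping to
#' the target within the contraction delay, and optional blink / ECG /
#' 50-Hz artifacts added to the EEG. The whole session is driven by a single
#' RNG stream keyed by `p$seed`, so identical parameters give bit-identical
#' recordings.
#'
#' @param p A `cmc_sim_params`.
#' @return A list with elements `recording` (a [new_recording()] object whose
#'   `meta` carries the montage, side, session and target electrode) and
#'   `truth` (a `cmc_sim_truth`: parameter echo, per-channel mixing gains and
#'   the closed-form [expected_coherence()] curve at the target electrode).
#' @export
simulate_session <- function(p) {
  validate_sim_params(p)
  kappa <- resolve_coupling(p)
  if (kappa == 0 && p$emg_noise_sd == 0) {
    stop("degenerate-signal error: coupling gain and EMG noise are both zero",
         call. = FALSE)
  }
  if (p$eeg_noise_sd == 0 && kappa == 0) {
    stop("degenerate-signal error: no coupling and no EEG noise", call. = FALSE)
  }
  mont <- sim_montage(p)
  target <- resolve_target(p, mont)
  set.seed(p$seed)

  fs <- p$fs
  trial_len <- round(p$trial_s * fs)
  slot_len <- round((p$trial_s + p$gap_s) * fs)
  n_tr <- p$n_trials * p$n_runs
  nsamp <- n_tr * slot_len

  # shared band-limited source via frequency-domain shaping of white noise
  w <- stats::rnorm(nsamp)
  fgrid <- (seq_len(nsamp) - 1) * fs / nsamp
  fgrid <- pmin(fgrid, fs - fgrid)
  Aw <- source_amplitude(p, fgrid)
  s <- Re(stats::fft(stats::fft(w) * Aw, inverse = TRUE)) / nsamp

  delay <- round(p$conduction_delay_ms / 1000 * fs)
  s_del <- if (delay > 0) c(s[(nsamp - delay + 1):nsamp], s[1:(nsamp - delay)]) else s

  # trial bookkeeping (0-based samples, [start, end) windows)
  starts <- (seq_len(n_tr) - 1L) * slot_len
  ends <- starts + trial_len
  events <- tibble::tibble(
    sample = as.integer(rbind(starts, ends)),
    code = rep(c("trial_start", "trial_end"), n_tr)
  )

  # contraction envelope: ramp over the contraction delay, hold, release
  env <- numeric(nsamp)
  ramp_len <- round(p$contraction_delay_s * fs)
  ramp <- seq(0, 1, length.out = ramp_len)
  for (i in seq_len(n_tr)) {
    a <- starts[i] + 1L
    env[a:(a + ramp_len - 1L)] <- ramp
    env[(a + ramp_len):(starts[i] + trial_len)] <- 1
  }

  # EEG: spatial gains from great-circle distance to the target; filled in
  # column blocks to keep peak memory near one channels x samples matrix
  g <- unname(exp(-p$spatial_decay * montage_distances(mont, target)))
  nch <- length(g)
  data <- matrix(0, nch + 2L, nsamp)
  blk <- max(1L, floor(8e6 / nch))
  for (a in seq(1L, nsamp, by = blk)) {
    b <- min(a + blk - 1L, nsamp)
    data[seq_len(nch), a:b] <-
      outer(g, s[a:b]) + stats::rnorm(nch * (b - a + 1L), sd = p$eeg_noise_sd)
  }

  if (isTRUE(p$artifacts$blink)) {
    data[seq_len(nch), ] <- data[seq_len(nch), ] + sim_blinks(p, mont, nsamp)
  }
  if (isTRUE(p$artifacts$ecg)) {
    data[seq_len(nch), ] <- data[seq_len(nch), ] + sim_ecg(p, mont, nsamp)
  }
  if (isTRUE(p$artifacts$line50)) {
    data[seq_len(nch), ] <- data[seq_len(nch), ] + sim_line(p, mont, nsamp)
  }

  # EMG: delayed coupled source + noise, gated by the contraction envelope
  data[nch + 1L, ] <- (kappa * s_del + stats::rnorm(nsamp, sd = p$emg_noise_sd)) *
    pmax(env, 0.02)

  # force: ramp to target then hold with small jitter, zero in gaps
  force <- env * p$force_n
  hold <- env == 1
  force[hold] <- force[hold] + stats::rnorm(sum(hold), sd = 0.05)
  data[nch + 2L, ] <- pmax(force, 0)

  rec <- new_recording(
    data, fs = fs,
    labels = c(mont$label, "EMG", "FORCE"),
    kinds = c(rep("EEG", nrow(mont)), "EMG", "FORCE"),
    events = events,
    meta = list(side = p$side, session = p$session, montage = mont,
                target_electrode = target, n_trials_per_run = p$n_trials)
  )
  truth <- structure(
    list(params = p, target_electrode = target,
         gains = tibble::tibble(label = mont$label, gain = unname(g)),
         expected = expected_coherence(p, target)),
    class = "cmc_sim_truth"
  )
  list(recording = rec, truth = truth)
}

# ~0.3 Hz Poisson blink train, frontal-weighted raised-cosine lobes
sim_blinks <- function(p, mont, nsamp) {
  fs <- p$fs
  n_blink <- stats::rpois(1, nsamp / fs * 0.3)
  out <- matrix(0, nrow(mont), nsamp)
  if (n_blink == 0) return(out)
  lobe_len <- round(0.3 * fs)
  lobe <- 60 * (0.5 - 0.5 * cos(2 * pi * seq_len(lobe_len) / lobe_len))
  tc <- numeric(nsamp)
  at <- sort(sample.int(nsamp - lobe_len, n_blink))
  for (a in at) tc[a:(a + lobe_len - 1L)] <- tc[a:(a + lobe_len - 1L)] + lobe
  wfront <- pmax(0, mont$y)^2
  out + outer(wfront, tc)
}

# ~1.2 Hz spike train broadcast at low, spatially smooth gain
sim_ecg <- function(p, mont, nsamp) {
  fs <- p$fs
  period <- fs / 1.2
  at <- round(seq(period / 2, nsamp - 3 * 0.02 * fs, by = period))
  at <- at + round(stats::rnorm(length(at), sd = period * 0.02))
  at <- at[at > 0 & at < nsamp - round(0.04 * fs)]
  spike_len <- round(0.02 * fs)
  spike <- 8 * sin(pi * seq_len(spike_len) / spike_len) *
    sign(sin(2 * pi * seq_len(spike_len) / spike_len))
  tc <- numeric(nsamp)
  for (a in at) tc[a:(a + spike_len - 1L)] <- tc[a:(a + spike_len - 1L)] + spike
  gains <- stats::runif(nrow(mont), 0.2, 0.5)
  outer(gains, tc)
}

# 50 Hz mains with random per-channel gain and common phase
sim_line <- function(p, mont, nsamp) {
  t <- (seq_len(nsamp) - 1) / p$fs
  phase <- stats::runif(1, 0, 2 * pi)
  tc <- 4 * sin(2 * pi * 50 * t + phase)
  gains <- stats::runif(nrow(mont), 0.5, 1.5)
  outer(gains, tc)
}

#' @export
print.cmc_sim_truth <- function(x, ...) {
  cat("<cmc_sim_truth> target ", x$target_electrode,
      ", kappa = ", resolve_coupling(x$params),
      ", peaks at ", paste(x$params$peak_freqs_hz, collapse = "/"), " Hz\n",
      sep = "")
  invisible(x)
}
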