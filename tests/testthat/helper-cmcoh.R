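# Shared fixtures and independent oracles for the test suite.

# small coupled session: 16 electrodes, one run of a few trials
tiny_session <- function(seed = 1, n_trials = 3, montage_size = 16, ...) {
  simulate_session(sim_params(montage_size = montage_size, n_trials = n_trials,
                              n_runs = 1, seed = seed, ...))
}

# hand-built epoch set (for partition tests where content must be traceable)
manual_epochs <- function(data, fs = 1000, labels = NULL, kinds = NULL,
                          condition = "cond") {
  d <- dim(data)
  labels <- labels %||% c(sprintf("E%03d", seq_len(d[1] - 1)), "EMG")
  kinds <- kinds %||% c(rep("EEG", d[1] - 1), "EMG")
  structure(
    list(data = data, fs = fs, labels = labels, kinds = kinds,
         condition = condition,
         provenance = tibble::tibble(epoch = seq_len(d[3]), run = 1,
                                     trial = seq_len(d[3])),
         meta = list()),
    class = "cmc_epochs"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent multitaper coherence oracle: explicit double-loop DFT, no FFT
brute_coherence <- function(x, y, tapers) {
  N <- nrow(x)
  L <- ncol(x)
  K <- ncol(tapers)
  nf <- floor(N / 2) + 1
  Sxy <- complex(nf)
  Sxx <- numeric(nf)
  Syy <- numeric(nf)
  for (fi in seq_len(nf)) {
    w <- exp(-2i * pi * (fi - 1) * (0:(N - 1)) / N)
    for (l in seq_len(L)) {
      for (k in seq_len(K)) {
        X <- sum(x[, l] * tapers[, k] * w)
        Y <- sum(y[, l] * tapers[, k] * w)
        Sxy[fi] <- Sxy[fi] + X * Conj(Y)
        Sxx[fi] <- Sxx[fi] + Mod(X)^2
        Syy[fi] <- Syy[fi] + Mod(Y)^2
      }
    }
  }
  Mod(Sxy) / sqrt(Sxx * Syy)
}

# band power of one channel by direct periodogram
band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  P <- Mod(stats::fft(x))^2
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  sum(P[f >= lo & f <= hi])
}

# independent evaluation of the z-spectrum formula using the log form of
# atanh, kept separate from the package's implementation
z_oracle <- function(C1, C2, d1, d2) {
  n1 <- 1 / (d1 - 2)
  n2 <- 1 / (d2 - 2)
  at <- function(r) 0.5 * (log1p(r) - log1p(-r))
  ((at(C1) - n1) - (at(C2) - n2)) / sqrt(n1 + n2)
}
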