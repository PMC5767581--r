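#' Multitaper coherence between two channels of an epoch set
#'
#' For every epoch `l` and Slepian taper `j`, tapered DFTs `X_lj(f)` and
#' `Y_lj(f)` are formed; cross- and auto-spectra are averaged over all
#' `(l, j)` pairs and the magnitude coherence is
#' `C(f) = |S_xy| / sqrt(S_xx S_yy)`. With `L` epochs and `K` tapers the
#' estimate carries `d = 2 K L` degrees of freedom, the quantity the
#' downstream z-transform uses. One-second epochs give a 1-Hz grid.
#'
#' @param ep A `cmc_epochs`.
#' @param eeg,emg Channel labels for the two signals (any two channels may
#'   be paired; the EMG is used unrectified).
#' @param nw,k Multitaper time-bandwidth product and taper count
#'   (defaults 2 and 3: +/-2 Hz smoothing on 1-s epochs).
#' @param ep2 Optional second epoch set supplying the `emg` channel when the
#'   two signals live in different objects (epoch counts must match).
#' @return A tibble of class `cmc_coherence` with columns `freq`,
#'   `coherence` (magnitude) and `coherence_sq`, and attributes `pair`, `d`,
#'   `L`, `K`, `fs`.
#' @export
coherence_spectrum <- function(ep, eeg, emg = "EMG", nw = 2, k = 3,
                               ep2 = NULL) {
  x <- epoch_channel(ep, eeg)
  y <- epoch_channel(ep2 %||% ep, emg)
  if (ncol(x) != ncol(y) || nrow(x) != nrow(y)) {
    stop("pairing error: channels have mismatched epoch counts or lengths",
         call. = FALSE)
  }
  if (stats::var(as.vector(x)) == 0 || stats::var(as.vector(y)) == 0) {
    stop("degenerate-signal error: zero-variance channel", call. = FALSE)
  }
  L <- ncol(x)
  if (L * k < 2) stop("pairing error: need L*K >= 2 estimates", call. = FALSE)
  tp <- make_tapers(nrow(x), nw, k)
  n_keep <- floor(nrow(x) / 2) + 1L
  X <- tapered_fft(x, tp, n_keep)
  Y <- tapered_fft(y, tp, n_keep)
  Sxy <- rowMeans(X * Conj(Y), dims = 1)
  Sxx <- rowMeans(Mod(X)^2, dims = 1)
  Syy <- rowMeans(Mod(Y)^2, dims = 1)
  C <- Mod(Sxy) / sqrt(Sxx * Syy)
  freqs <- (seq_len(n_keep) - 1) * ep$fs / nrow(x)
  out <- tibble::tibble(freq = freqs, coherence = C, coherence_sq = C^2)
  class(out) <- c("cmc_coherence", class(out))
  attr(out, "pair") <- c(eeg, emg)
  attr(out, "d") <- 2 * k * L
  attr(out, "L") <- L
  attr(out, "K") <- k
  attr(out, "fs") <- ep$fs
  out
}

#' @export
print.cmc_coherence <- function(x, ...) {
  pr <- attr(x, "pair")
  cat("<cmc_coherence> ", pr[1], " ~ ", pr[2], ", L = ", attr(x, "L"),
      " epochs, K = ", attr(x, "K"), " tapers, d = ", attr(x, "d"), "\n",
      sep = "")
  NextMethod()
}

check_band <- function(freqs, band) {
  if (length(band) != 2 || band[1] >= band[2]) {
    stop("band error: band must be (low, high) with low < high", call. = FALSE)
  }
  sel <- freqs >= band[1] & freqs <= band[2]
  if (!any(sel) || band[2] > max(freqs)) {
    stop("band error: band [", band[1], ", ", band[2],
         "] Hz outside the frequency grid (0-", max(freqs), " Hz)",
         call. = FALSE)
  }
  sel
}

#' Band-averaged coherence topography
#'
#' Mean coherence over a frequency band (endpoints inclusive) for every EEG
#' electrode, with the peak electrode recorded (ties broken by first
#' montage/input order). The default band is beta, 15-30 Hz.
#'
#' @param x A `cmc_epochs` (coherence of every EEG electrode against `emg`
#'   is computed) or a named list of `cmc_coherence` spectra sharing one
#'   frequency grid.
#' @param band Frequency band `(low, high)` in Hz.
#' @param ... Passed on between methods.
#' @return A tibble of class `cmc_topography` with columns `electrode`,
#'   `coherence` (and `x`, `y`, `z` when montage positions are known), plus
#'   attributes `band` and `peak_electrode`.
#' @export
band_topography <- function(x, band = c(15, 30), ...) {
  UseMethod("band_topography")
}

#' @rdname band_topography
#' @param emg EMG reference channel label.
#' @param nw,k Multitaper parameters.
#' @param csd Optional `cmc_csd` operator. The surface Laplacian is a linear
#'   channel mix applied sample-wise, so it commutes with tapering and the
#'   DFT; supplying it here applies the operator to the tapered spectra
#'   directly, which equals running [apply_csd()] first but avoids a second
#'   pass over the time series.
#' @export
band_topography.cmc_epochs <- function(x, band = c(15, 30), emg = "EMG",
                                       nw = 2, k = 3, csd = NULL, ...) {
  ep <- x
  eeg_idx <- which(ep$kinds == "EEG")
  nch <- length(eeg_idx)
  if (!is.null(csd) && !identical(ep$labels[eeg_idx], csd$montage$label)) {
    stop("montage-mismatch error: epoch EEG channels do not match the ",
         "operator's montage", call. = FALSE)
  }
  N <- dim(ep$data)[2]
  L <- dim(ep$data)[3]
  tp <- make_tapers(N, nw, k)
  n_keep <- floor(N / 2) + 1L
  freqs <- (seq_len(n_keep) - 1) * ep$fs / N
  sel <- which(check_band(freqs, band))
  nb <- length(sel)

  Y <- tapered_fft(epoch_channel(ep, emg), tp, n_keep)[sel, , , drop = FALSE]
  Syy <- rowMeans(Mod(Y)^2, dims = 1)

  # one pass over all EEG channels: samples x (channels * epochs), with the
  # DFT evaluated only at the band bins (BLAS product; tapers folded in)
  big <- matrix(aperm(ep$data[eeg_idx, , , drop = FALSE], c(2, 1, 3)),
                nrow = N)
  # X[b, ch, l, j]: band-limited tapered spectra
  X <- array(tapered_dft_bins(big, tp, sel), dim = c(nb, nch, L, k))
  if (!is.null(csd)) {
    # apply the Laplacian to the spectra (channel dim second)
    Xm <- matrix(aperm(X, c(2, 1, 3, 4)), nrow = nch)
    X <- aperm(array(csd$operator %*% Xm, dim = c(nch, nb, L, k)),
               c(2, 1, 3, 4))
  }
  vals <- vapply(seq_len(nch), function(ci) {
    Xc <- array(X[, ci, , , drop = FALSE], dim = c(nb, L, k))
    Sxy <- rowMeans(Xc * Conj(Y), dims = 1)
    Sxx <- rowMeans(Mod(Xc)^2, dims = 1)
    mean(Mod(Sxy) / sqrt(Sxx * Syy))
  }, numeric(1))

  out <- tibble::tibble(electrode = ep$labels[eeg_idx], coherence = vals)
  mont <- ep$meta$montage
  if (!is.null(mont) && all(out$electrode %in% mont$label)) {
    mi <- match(out$electrode, mont$label)
    out$x <- mont$x[mi]; out$y <- mont$y[mi]; out$z <- mont$z[mi]
  }
  new_topography(out, band)
}

#' @rdname band_topography
#' @export
band_topography.list <- function(x, band = c(15, 30), ...) {
  stopifnot(length(x) > 0, all(vapply(x, inherits, TRUE, "cmc_coherence")))
  f0 <- x[[1]]$freq
  for (co in x) {
    if (!isTRUE(all.equal(co$freq, f0))) {
      stop("pairing error: coherence spectra on different frequency grids",
           call. = FALSE)
    }
  }
  sel <- check_band(f0, band)
  labs <- names(x) %||% vapply(x, function(co) attr(co, "pair")[1], "")
  out <- tibble::tibble(
    electrode = labs,
    coherence = vapply(x, function(co) mean(co$coherence[sel]), numeric(1))
  )
  new_topography(out, band)
}

new_topography <- function(df, band) {
  class(df) <- c("cmc_topography", class(df))
  attr(df, "band") <- band
  attr(df, "peak_electrode") <- df$electrode[which.max(df$coherence)]
  df
}

#' @export
print.cmc_topography <- function(x, ...) {
  b <- attr(x, "band")
  cat("<cmc_topography> band ", b[1], "-", b[2], " Hz, peak at ",
      attr(x, "peak_electrode"), "\n", sep = "")
  NextMethod()
}

#' Per-session coherence spectrum at the session's own peak electrode
#'
#' Statistical comparisons are based on the spectrum at the electrode where
#' the strongest beta-band coupling emerged; because the peak location may
#' shift slightly between sessions (e.g. cap placement), the peak electrode
#' is selected per session rather than shared.
#'
#' @param sessions A named list of `cmc_epochs`, one per session.
#' @param band Band used for peak selection.
#' @param emg EMG channel label.
#' @param nw,k Multitaper parameters.
#' @return A named list (same names as `sessions`) of `cmc_coherence`
#'   spectra at each session's peak electrode, with a `peaks` attribute
#'   tabulating the selected electrodes.
#' @export
select_peak_spectrum <- function(sessions, band = c(15, 30), emg = "EMG",
                                 nw = 2, k = 3) {
  stopifnot(length(sessions) >= 1,
            all(vapply(sessions, inherits, TRUE, "cmc_epochs")))
  topos <- lapply(sessions, band_topography, band = band, emg = emg,
                  nw = nw, k = k)
  peaks <- unname(vapply(topos, attr, "", "peak_electrode"))
  out <- lapply(seq_along(sessions), function(i) {
    coherence_spectrum(sessions[[i]], peaks[i], emg, nw = nw, k = k)
  })
  names(out) <- names(sessions) %||%
    vapply(sessions, function(s) s$condition, "")
  attr(out, "peaks") <- tibble::tibble(
    session = names(out) %||% as.character(seq_along(out)),
    electrode = unname(peaks)
  )
  out
}
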