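#' Design a linear-phase FIR band-pass kernel
#'
#' Hamming-windowed sinc design via [signal::fir1()], with the filter order
#' chosen as `ceiling(3.3 * fs / 1)` (rounded up to even so the tap count is
#' odd and the filter is type-I symmetric). This meets a transition width of
#' about 1 Hz at the low edge and >= 40 dB attenuation at `low/2` and at
#' `high + 5` Hz for the default 3-45 Hz band at 1000 Hz.
#'
#' @param fs Sampling rate, Hz.
#' @param low,high Pass-band edges, Hz (`0 < low < high < fs/2`).
#' @return A list of class `cmc_fir` with elements `coef` (symmetric taps),
#'   `fs` and `band`.
#' @export
design_bandpass <- function(fs, low = 3, high = 45) {
  if (!(low > 0 && low < high && high < fs / 2)) {
    stop("filter design error: need 0 < low < high < fs/2 (got ",
         low, ", ", high, " at fs = ", fs, ")", call. = FALSE)
  }
  ord <- ceiling(3.3 * fs / 1)
  if (ord %% 2 == 1) ord <- ord + 1
  b <- signal::fir1(ord, c(low, high) / (fs / 2), type = "pass")
  structure(list(coef = as.numeric(b), fs = fs, band = c(low, high)),
            class = "cmc_fir")
}

#' Frequency response of an FIR kernel
#'
#' Direct evaluation of `H(f) = sum_j b_j exp(-2i pi f j / fs)`.
#'
#' @param kernel A `cmc_fir`.
#' @param freqs Frequencies in Hz.
#' @param twopass If `TRUE`, return the squared-magnitude (forward-backward)
#'   response.
#' @return Numeric vector of gain magnitudes.
#' @export
fir_response <- function(kernel, freqs, twopass = FALSE) {
  j <- seq_along(kernel$coef) - 1
  H <- vapply(freqs, function(f) {
    Mod(sum(kernel$coef * exp(-2i * pi * f * j / kernel$fs)))
  }, numeric(1))
  if (twopass) H^2 else H
}

# causal FIR filtering of a vector by FFT convolution, output aligned to x
fir_causal <- function(b, x, B = NULL, nfft = NULL) {
  n <- length(x)
  nfft <- nfft %||% stats::nextn(n + length(b) - 1, c(2, 3, 5))
  if (is.null(B)) B <- stats::fft(c(b, numeric(nfft - length(b))))
  X <- stats::fft(c(x, numeric(nfft - n)))
  Re(stats::fft(X * B, inverse = TRUE))[seq_len(n)] / nfft
}

# forward-backward zero-phase filtering with odd-reflection padding of one
# kernel length at each edge
filtfilt_vec <- function(b, x) {
  p <- length(b)
  n <- length(x)
  xp <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  nfft <- stats::nextn(length(xp) + p - 1, c(2, 3, 5))
  B <- stats::fft(c(b, numeric(nfft - p)))
  y <- fir_causal(b, xp, B = B, nfft = nfft)
  y <- rev(fir_causal(b, rev(y), B = B, nfft = nfft))
  y[(p + 1):(p + n)]
}

#' Two-pass (zero-phase) FIR filtering of a recording
#'
#' Filters every EEG and EMG channel forward then backward, so the effective
#' magnitude response is the squared kernel response and the net phase is
#' zero. Edges are handled by odd-reflection padding of one kernel length.
#' FORCE channels pass through unfiltered. EMG is filtered with the same
#' band as EEG and is not rectified.
#'
#' @param rec A `cmc_recording` (or a bare numeric vector, filtered as-is).
#' @param kernel A `cmc_fir` from [design_bandpass()] with matching `fs`.
#' @return The filtered recording (or vector).
#' @export
filter_twopass <- function(rec, kernel) {
  stopifnot(inherits(kernel, "cmc_fir"))
  if (is.numeric(rec) && is.null(dim(rec))) {
    if (length(rec) < 3 * length(kernel$coef)) {
      stop("length error: signal must be at least 3 kernel lengths (",
           3 * length(kernel$coef), " samples)", call. = FALSE)
    }
    return(filtfilt_vec(kernel$coef, rec))
  }
  validate_recording(rec)
  if (rec$fs != kernel$fs) {
    stop("filter error: kernel designed for fs = ", kernel$fs,
         " but recording has fs = ", rec$fs, call. = FALSE)
  }
  if (ncol(rec$data) < 3 * length(kernel$coef)) {
    stop("length error: signal must be at least 3 kernel lengths (",
         3 * length(kernel$coef), " samples)", call. = FALSE)
  }
  out <- rec
  for (ch in seq_len(nrow(rec$data))) {
    if (rec$kinds[ch] == "FORCE") next
    out$data[ch, ] <- filtfilt_vec(kernel$coef, rec$data[ch, ])
  }
  out$meta$filtered <- kernel$band
  out
}
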