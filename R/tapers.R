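#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `k` DPSS sequences of length `n` for time-bandwidth
#' product `nw`, via the eigenvectors of the standard symmetric tridiagonal
#' matrix (whose eigenvectors coincide with the Slepian sequences, ordered
#' by spectral concentration). Tapers are unit-norm and mutually orthogonal;
#' taper `j` has exactly `j - 1` sign changes. Results are cached per
#' `(n, nw, k)`.
#'
#' @param n Taper length in samples (>= 8).
#' @param nw Time-bandwidth product (half-bandwidth `nw / (n * dt)` Hz).
#' @param k Number of tapers, `1 <= k <= 2 * nw - 1`.
#' @return An `n` x `k` matrix of class `cmc_tapers` with attributes `nw`
#'   and `k`.
#' @export
make_tapers <- function(n, nw = 2, k = 3) {
  if (n < 8) stop("taper parameter error: n must be >= 8", call. = FALSE)
  if (k < 1 || k > 2 * nw - 1) {
    stop("taper parameter error: need 1 <= k <= 2*nw - 1 (k = ", k,
         ", nw = ", nw, ")", call. = FALSE)
  }
  key <- paste(n, nw, k, sep = "_")
  if (!is.null(the$tapers[[key]])) return(the$tapers[[key]])
  w <- nw / n
  t <- 0:(n - 1)
  diag_v <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * w)
  off <- t[-1] * (n - t[-1]) / 2
  M <- matrix(0, n, n)
  diag(M) <- diag_v
  M[cbind(1:(n - 1), 2:n)] <- off
  M[cbind(2:n, 1:(n - 1))] <- off
  eg <- eigen(M, symmetric = TRUE)
  V <- eg$vectors[, seq_len(k), drop = FALSE]
  # sign convention: symmetric tapers have positive mean, antisymmetric
  # tapers start with a positive lobe
  for (j in seq_len(k)) {
    s <- sum(V[, j])
    s <- if (abs(s) > 1e-8) s else sum(V[seq_len(ceiling(n / 2)), j])
    if (s < 0) V[, j] <- -V[, j]
  }
  out <- structure(V, nw = nw, k = k, class = "cmc_tapers")
  if (is.null(the$tapers)) the$tapers <- list()
  the$tapers[[key]] <- out
  out
}

# tapered DFTs of a samples x epochs matrix for every taper; returns the
# per-epoch taper-summed auto/cross building blocks used by the coherence
# estimators: a freq x epochs x k complex array.
tapered_fft <- function(xmat, tapers, n_keep) {
  n <- nrow(xmat)
  k <- ncol(tapers)
  out <- array(0i, dim = c(n_keep, ncol(xmat), k))
  for (j in seq_len(k)) {
    out[, , j] <- stats::mvfft(xmat * tapers[, j])[seq_len(n_keep), , drop = FALSE]
  }
  out
}

# band-limited tapered DFT of a samples x columns matrix, evaluated only at
# the requested frequency bins via two real matrix products per taper (the
# tapers are folded into the DFT matrix, so the data are touched once);
# equal to tapered_fft(...)[bins, , ] up to float round-off
tapered_dft_bins <- function(xmat, tapers, bins, fs_unused = NULL) {
  n <- nrow(xmat)
  k <- ncol(tapers)
  t_id <- 0:(n - 1)
  out <- array(0i, dim = c(length(bins), ncol(xmat), k))
  ang <- -2 * pi * outer(bins - 1, t_id) / n
  Fre <- cos(ang)
  Fim <- sin(ang)
  for (j in seq_len(k)) {
    Fr <- Fre * rep(tapers[, j], each = length(bins))
    Fi <- Fim * rep(tapers[, j], each = length(bins))
    out[, , j] <- (Fr %*% xmat) + 1i * (Fi %*% xmat)
  }
  out
}
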