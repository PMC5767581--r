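# Deterministic symmetric fixed-point ICA with tanh contrast, operating on
# the EEG channels of a recording. Any algorithm meeting the reconstruction
# and determinism contracts would be conformant; the fixed-point scheme is
# used because it is fast, seedable and has no stochastic updates beyond the
# seeded initial rotation.

#' Fit an ICA decomposition of the EEG channels
#'
#' Whitens the (row-centred) EEG data by PCA and runs symmetric fixed-point
#' ICA with a `tanh` nonlinearity from a seeded random orthogonal start.
#' Components are ordered by explained variance (descending) and the sign of
#' each mixing column is fixed so its largest-magnitude entry is positive,
#' making the result reproducible bit-for-bit for a given seed.
#'
#' @param rec A `cmc_recording`; only EEG channels enter the decomposition.
#' @param n_components Number of components; default all EEG channels.
#' @param seed Seed for the initial rotation.
#' @param max_iter,tol Fixed-point iteration controls.
#' @return An object of class `cmc_ica` with fields `unmixing`
#'   (components x channels), `mixing` (channels x components,
#'   pseudo-inverse of `unmixing`), `sources` (components x samples),
#'   `center` (per-channel means), `eeg_idx` and `labels`.
#' @export
fit_ica <- function(rec, n_components = NULL, seed = 1L, max_iter = 200,
                    tol = 1e-8) {
  validate_recording(rec)
  eeg_idx <- which(rec$kinds == "EEG")
  X <- rec$data[eeg_idx, , drop = FALSE]
  nch <- nrow(X)
  ns <- ncol(X)
  if (ns < 20 * nch) {
    stop("ICA error: need at least 20 samples per channel (",
         20 * nch, "), got ", ns, call. = FALSE)
  }
  nc <- n_components %||% nch
  ctr <- rowMeans(X)
  X <- X - ctr

  cv <- tcrossprod(X) / (ns - 1)
  eg <- eigen(cv, symmetric = TRUE)
  rank_tol <- max(eg$values) * 1e-10
  rank <- sum(eg$values > rank_tol)
  if (rank < nc) {
    stop("rank error: EEG data has numerical rank ", rank, " < ", nc,
         " requested components (duplicated or linearly dependent channels);",
         " reduce n_components", call. = FALSE)
  }
  E <- eg$vectors[, seq_len(nc), drop = FALSE]
  D <- eg$values[seq_len(nc)]
  wh <- t(E) / sqrt(D)          # nc x nch whitening
  dewh <- E * rep(sqrt(D), each = nch)  # nch x nc
  Z <- wh %*% X

  sym_decorrelate <- function(W) {
    s <- eigen(tcrossprod(W), symmetric = TRUE)
    s$vectors %*% diag(1 / sqrt(s$values), nc) %*% t(s$vectors) %*% W
  }
  set.seed(seed)
  W <- sym_decorrelate(matrix(stats::rnorm(nc * nc), nc))
  for (it in seq_len(max_iter)) {
    Y <- W %*% Z
    G <- tanh(Y)
    gprime <- rowMeans(1 - G^2)
    W1 <- tcrossprod(G, Z) / ns - diag(gprime, nc) %*% W
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(1 - abs(rowSums(W1 * W))))
    W <- W1
    if (delta < tol) break
  }
  # band-limited Gaussian background activity has no unique ICA rotation, so
  # the Gaussian subspace may keep rotating; the artifact components of
  # interest (non-Gaussian) stabilise long before max_iter
  if (delta >= tol) {
    message("fit_ica: stopped after ", max_iter,
            " iterations (residual rotation ", format(delta, digits = 3), ")")
  }

  unmix <- W %*% wh            # nc x nch, in original channel space
  mix <- dewh %*% t(W)         # nch x nc; unmix %*% mix = I
  # order by explained variance; sources have unit variance under whitening
  expl <- colSums(mix^2)
  ord <- order(expl, decreasing = TRUE)
  unmix <- unmix[ord, , drop = FALSE]
  mix <- mix[, ord, drop = FALSE]
  # deterministic sign: largest |mixing| entry positive
  for (j in seq_len(nc)) {
    s <- sign(mix[which.max(abs(mix[, j])), j])
    if (s < 0) { mix[, j] <- -mix[, j]; unmix[j, ] <- -unmix[j, ] }
  }
  structure(
    list(unmixing = unmix, mixing = mix, sources = unmix %*% X,
         center = ctr, eeg_idx = eeg_idx, labels = rec$labels[eeg_idx],
         n_components = nc, explained = sort(expl, decreasing = TRUE),
         seed = seed, iterations = it),
    class = "cmc_ica"
  )
}

#' @export
print.cmc_ica <- function(x, ...) {
  cat("<cmc_ica> ", x$n_components, " components over ", length(x$labels),
      " EEG channels (", x$iterations, " iterations)\n", sep = "")
  invisible(x)
}

# smooth FFT low-pass used by the blink score (pass below f_lo, cosine
# roll-off to f_hi)
fft_lowpass <- function(x, fs, f_lo = 4, f_hi = 6) {
  n <- length(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  gain <- ifelse(f <= f_lo, 1,
                 ifelse(f >= f_hi, 0, 0.5 + 0.5 * cos(pi * (f - f_lo) / (f_hi - f_lo))))
  Re(stats::fft(stats::fft(x) * gain, inverse = TRUE)) / n
}

#' Score ICA components for blink, ECG and line-noise artifacts
#'
#' Three scores in `[0, 1]` per component:
#' * `blink`: absolute correlation of the component time course with the
#'   low-passed (< 5 Hz) average of the frontal electrodes (anterior third of
#'   the montage when positions are available, otherwise all EEG channels).
#' * `ecg`: regularity of a detected peak train — the fraction of
#'   inter-peak intervals within 20% of their median, provided the mean rate
#'   falls in 0.8-2 Hz (otherwise 0).
#' * `line`: fraction of total component power within 50 +/- 1 Hz.
#'
#' @param ica A `cmc_ica` fitted on `rec`.
#' @param rec The recording the decomposition was fitted on.
#' @return A tibble with columns `component`, `blink`, `ecg`, `line`.
#' @export
score_artifacts <- function(ica, rec) {
  stopifnot(inherits(ica, "cmc_ica"))
  validate_recording(rec)
  fs <- rec$fs
  eeg <- rec$data[ica$eeg_idx, , drop = FALSE]
  mont <- rec$meta$montage
  if (!is.null(mont) && all(ica$labels %in% mont$label)) {
    y <- mont$y[match(ica$labels, mont$label)]
    frontal <- which(y > stats::quantile(y, 2 / 3))
  } else {
    frontal <- seq_len(nrow(eeg))
  }
  ref <- fft_lowpass(colMeans(eeg[frontal, , drop = FALSE]), fs)

  out <- lapply(seq_len(ica$n_components), function(j) {
    src <- ica$sources[j, ]
    if (stats::sd(src) == 0) {
      return(tibble::tibble(component = j, blink = 0, ecg = 0, line = 0))
    }
    blink <- if (stats::sd(ref) > 0) abs(stats::cor(src, ref)) else 0

    # ECG: peak train regularity in 0.8-2 Hz
    thr <- 4 * stats::mad(src)
    above <- which(abs(src) > thr)
    ecg <- 0
    if (length(above) > 3) {
      gaps <- which(diff(above) > 0.2 * fs)
      peaks <- above[c(1L, gaps + 1L)]
      if (length(peaks) >= 4) {
        iv <- diff(peaks) / fs
        rate <- 1 / stats::median(iv)
        if (rate >= 0.8 && rate <= 2) {
          ecg <- mean(abs(iv - stats::median(iv)) <= 0.2 * stats::median(iv))
        }
      }
    }

    # line: power fraction in 50 +/- 1 Hz
    n <- length(src)
    P <- Mod(stats::fft(src))^2
    f <- (seq_len(n) - 1) * fs / n
    f <- pmin(f, fs - f)
    line <- sum(P[f >= 49 & f <= 51]) / sum(P[f > 0 & f <= fs / 2 & f >= 0])
    tibble::tibble(component = j, blink = blink, ecg = ecg,
                   line = min(1, line))
  })
  dplyr::bind_rows(out)
}

#' Remove ICA components from a recording
#'
#' Subtracts the back-projection of the rejected components from the EEG
#' channels, so rejecting nothing returns the input exactly and rejecting a
#' set of artifact components removes only their subspace.
#'
#' @param rec The recording the decomposition was fitted on.
#' @param ica A `cmc_ica`.
#' @param reject Integer indices of components to remove.
#' @return The cleaned `cmc_recording`.
#' @export
remove_components <- function(rec, ica, reject) {
  stopifnot(inherits(ica, "cmc_ica"))
  validate_recording(rec)
  reject <- as.integer(reject)
  if (length(reject) && (min(reject) < 1 || max(reject) > ica$n_components)) {
    stop("ICA error: reject indices outside fitted components", call. = FALSE)
  }
  if (length(unique(reject)) >= ica$n_components) {
    stop("degenerate-output error: rejecting every component leaves no signal",
         call. = FALSE)
  }
  out <- rec
  if (length(reject)) {
    art <- ica$mixing[, reject, drop = FALSE] %*%
      ica$sources[reject, , drop = FALSE]
    out$data[ica$eeg_idx, ] <- rec$data[ica$eeg_idx, ] - art
  }
  out$meta$ica_rejected <- reject
  out
}

#' Automatic artifact rejection
#'
#' Fits ICA, scores every component and removes those whose blink, ECG or
#' line score exceeds `threshold`.
#'
#' @inheritParams fit_ica
#' @param threshold Rejection threshold on all three scores (default 0.7).
#' @return The cleaned recording, with the scores in `meta$ica_scores`.
#' @export
clean_artifacts <- function(rec, n_components = NULL, seed = 1L,
                            threshold = 0.7) {
  ica <- fit_ica(rec, n_components = n_components, seed = seed)
  sc <- score_artifacts(ica, rec)
  bad <- sc$component[sc$blink > threshold | sc$ecg > threshold |
                        sc$line > threshold]
  out <- if (length(bad)) remove_components(rec, ica, bad) else rec
  out$meta$ica_scores <- sc
  out$meta$ica_rejected <- bad
  out
}
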