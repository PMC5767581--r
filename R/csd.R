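# Spherical-spline surface Laplacian (current source density).
#
# The scalp is modelled as a unit sphere. Interpolation and Laplacian
# kernels are the Legendre series
#   g(x) = sum_{n=1}^{n_terms} (2n+1) / (n(n+1))^m     * P_n(x)
#   h(x) = sum_{n=1}^{n_terms} (2n+1) / (n(n+1))^(m-1) * P_n(x)
# with x = cos(angle between electrodes). Spline coefficients are obtained
# by solving (G + lambda I) c + c0 = v subject to sum(c) = 0, and the CSD at
# the electrodes is H c (source-positive: a focal positive potential gives a
# positive CSD at the focus with a negative surround).

# Legendre polynomials P_1..P_nmax evaluated at a matrix x, returned as a
# list accumulated into series sums; recurrence (n)P_n = (2n-1)xP_{n-1} - (n-1)P_{n-2}
legendre_series <- function(x, m, n_terms) {
  g <- array(0, dim = dim(x))
  h <- array(0, dim = dim(x))
  Pm2 <- array(1, dim = dim(x))  # P_0
  Pm1 <- x                       # P_1
  for (n in seq_len(n_terms)) {
    Pn <- if (n == 1) Pm1 else (((2 * n - 1) * x * Pm1 - (n - 1) * Pm2) / n)
    if (n > 1) { Pm2 <- Pm1; Pm1 <- Pn }
    nn1 <- n * (n + 1)
    g <- g + (2 * n + 1) / nn1^m * Pn
    h <- h + (2 * n + 1) / nn1^(m - 1) * Pn
  }
  list(g = g, h = h)
}

#' Build a spherical-spline CSD operator
#'
#' Precomputes the electrode-pair interpolation (`G`) and Laplacian (`H`)
#' matrices for a montage and assembles the solve-then-project machinery.
#' The operator is linear, annihilates spatially constant inputs, and
#' depends only on the montage and `(m, lambda, n_terms)`.
#'
#' @param mont A `cmc_montage`.
#' @param m Spline flexibility order (>= 2; default 4).
#' @param lambda Ridge regulariser added to the diagonal of `G`
#'   (default 1e-5).
#' @param n_terms Legendre series truncation (default 50).
#' @return An object of class `cmc_csd` holding the projection matrix
#'   (`operator`, channels x channels) and its ingredients.
#' @export
csd_operator <- function(mont, m = 4, lambda = 1e-5, n_terms = 50) {
  validate_montage(mont)
  if (m < 2) stop("CSD error: spline order m must be >= 2", call. = FALSE)
  if (lambda < 0) stop("CSD error: lambda must be >= 0", call. = FALSE)
  pos <- montage_positions(mont)
  n <- nrow(pos)
  ct <- pmin(pmax(tcrossprod(pos), -1), 1)
  if (any(ct[upper.tri(ct)] > 1 - 1e-12)) {
    stop("singularity error: montage contains coincident electrodes",
         call. = FALSE)
  }
  ser <- legendre_series(ct, m, n_terms)
  G <- ser$g
  H <- ser$h
  # constrained solve: [G + lambda I, 1; 1', 0] [c; c0] = [v; 0]
  Aug <- rbind(cbind(G + diag(lambda, n), 1), c(rep(1, n), 0))
  Ainv <- solve(Aug)
  Csolve <- Ainv[seq_len(n), seq_len(n), drop = FALSE]  # v -> c
  structure(
    list(operator = H %*% Csolve, G = G, H = H, montage = mont,
         m = m, lambda = lambda, n_terms = n_terms),
    class = "cmc_csd"
  )
}

# direct series value of g at cos(theta) = 1 (used as a self-check target)
csd_g_at_1 <- function(m = 4, n_terms = 50) {
  n <- seq_len(n_terms)
  sum((2 * n + 1) / (n * (n + 1))^m)
}

#' @export
print.cmc_csd <- function(x, ...) {
  cat("<cmc_csd> spherical-spline Laplacian over ", nrow(x$montage),
      " electrodes (m = ", x$m, ", lambda = ", format(x$lambda),
      ", ", x$n_terms, " terms)\n", sep = "")
  invisible(x)
}

#' Transform epoched EEG to current source density
#'
#' Applies the spherical-spline Laplacian sample-wise to the EEG channels of
#' an epoch set; EMG and FORCE channels pass through untouched. The output
#' is reference-free: adding any constant to all EEG channels leaves the
#' CSD unchanged (to numerical precision).
#'
#' @param ep A `cmc_epochs` whose EEG channel labels match the operator's
#'   montage (same order).
#' @param op A `cmc_csd` from [csd_operator()].
#' @return The transformed `cmc_epochs` (EEG now in CSD units, microvolts
#'   per unit solid angle on the unit sphere).
#' @export
apply_csd <- function(ep, op) {
  stopifnot(inherits(ep, "cmc_epochs"), inherits(op, "cmc_csd"))
  eeg_idx <- which(ep$kinds == "EEG")
  if (!identical(ep$labels[eeg_idx], op$montage$label)) {
    stop("montage-mismatch error: epoch EEG channels do not match the ",
         "operator's montage", call. = FALSE)
  }
  d <- dim(ep$data)
  out <- ep
  # transform epoch blocks in place to bound peak memory on long sessions
  chunk <- max(1L, floor(2e7 / (d[1] * d[2])))
  for (a in seq(1L, d[3], by = chunk)) {
    b <- min(a + chunk - 1L, d[3])
    flat <- matrix(ep$data[eeg_idx, , a:b, drop = FALSE],
                   nrow = length(eeg_idx))
    out$data[eeg_idx, , a:b] <- array(op$operator %*% flat,
                                      dim = c(length(eeg_idx), d[2], b - a + 1L))
  }
  out$meta$csd <- list(m = op$m, lambda = op$lambda, n_terms = op$n_terms)
  out
}
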