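#' Construct a coherence spectrum from values
#'
#' Wraps a frequency grid, coherence magnitudes and the degrees of freedom
#' into a `cmc_coherence` object, for use when the spectrum comes from an
#' external source rather than [coherence_spectrum()].
#'
#' @param freq Frequency grid, Hz (strictly increasing).
#' @param coherence Coherence magnitude in `[0, 1]`.
#' @param d Degrees of freedom of the estimate (`2 * K * L`).
#' @param pair Optional channel-pair labels.
#' @return A `cmc_coherence` tibble.
#' @export
as_coherence <- function(freq, coherence, d, pair = c("x", "y")) {
  stopifnot(length(freq) == length(coherence), !is.unsorted(freq, strictly = TRUE))
  if (any(coherence < 0 | coherence > 1)) {
    stop("coherence values must lie in [0, 1]", call. = FALSE)
  }
  out <- tibble::tibble(freq = freq, coherence = coherence,
                        coherence_sq = coherence^2)
  class(out) <- c("cmc_coherence", class(out))
  attr(out, "pair") <- pair
  attr(out, "d") <- d
  out
}

#' Bias-corrected z-spectrum of a coherence difference
#'
#' Transforms the coherence difference of two conditions to the z-statistic
#' spectrum
#' `Z(f) = ((atanh C1(f) - n1) - (atanh C2(f) - n2)) / sqrt(n1 + n2)`,
#' with bias/variance terms `n_i = 1 / (d_i - 2)` where `d_i` are the
#' degrees of freedom of the two estimates. This removes the unequal
#' estimation bias when the two conditions carry different numbers of
#' segments. Coherence is clipped at `1 - 1e-12` so the transform stays
#' finite.
#'
#' @param c1,c2 `cmc_coherence` objects on the same frequency grid.
#' @param d1,d2 Degrees of freedom; default taken from the objects.
#' @return A tibble of class `cmc_zspectrum` with columns `freq`, `z` and
#'   attributes `d1`, `d2`, `n1`, `n2`.
#' @export
z_difference <- function(c1, c2, d1 = attr(c1, "d"), d2 = attr(c2, "d")) {
  if (is.null(d1) || is.null(d2) || d1 <= 2 || d2 <= 2) {
    stop("dof error: both degrees of freedom must exceed 2", call. = FALSE)
  }
  if (!isTRUE(all.equal(c1$freq, c2$freq))) {
    stop("pairing error: coherence spectra on different frequency grids",
         call. = FALSE)
  }
  n1 <- 1 / (d1 - 2)
  n2 <- 1 / (d2 - 2)
  z <- z_values(c1$coherence, c2$coherence, n1, n2)
  out <- tibble::tibble(freq = c1$freq, z = z)
  class(out) <- c("cmc_zspectrum", class(out))
  attr(out, "d1") <- d1; attr(out, "d2") <- d2
  attr(out, "n1") <- n1; attr(out, "n2") <- n2
  out
}

z_values <- function(C1, C2, n1, n2) {
  C1 <- pmin(C1, 1 - 1e-12)
  C2 <- pmin(C2, 1 - 1e-12)
  ((atanh(C1) - n1) - (atanh(C2) - n2)) / sqrt(n1 + n2)
}

#' Supra-threshold clusters of adjacent frequencies
#'
#' Within the analysis band, maximal runs of consecutive frequencies whose
#' statistic exceeds the cluster-forming threshold (strict inequality)
#' become clusters; the cluster mass is the sum of member z-values.
#' Clustering over adjacent frequencies controls the multiple-comparison
#' problem across the spectrum. For the two-sided variant, positive and
#' negative excursions (`z > thr`, `z < -thr`) form separate clusters whose
#' mass is the summed `|z|`.
#'
#' @param z A `cmc_zspectrum` (or any tibble with `freq` and `z`).
#' @param threshold Cluster-forming threshold (> 0). The default 1.645 is
#'   the one-sided normal critical value at alpha = 0.05.
#' @param band Band restriction `(low, high)` Hz, endpoints inclusive.
#' @param alternative `"greater"` (one-sided, condition 1 above condition 2)
#'   or `"two.sided"`.
#' @return A tibble of class `cmc_clusters` with one row per cluster
#'   (`start_freq`, `end_freq`, `n_freqs`, `sign`, `mass`) and attributes
#'   `threshold` and `band`. Zero rows when nothing exceeds the threshold.
#' @export
find_clusters <- function(z, threshold = 1.645, band = c(15, 30),
                          alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (threshold <= 0) stop("cluster error: threshold must be > 0", call. = FALSE)
  sel <- check_band(z$freq, band)
  f <- z$freq[sel]
  zz <- z$z[sel]
  rows <- cluster_rows(zz, f, threshold, alternative)
  out <- rows
  class(out) <- c("cmc_clusters", class(out))
  attr(out, "threshold") <- threshold
  attr(out, "band") <- band
  attr(out, "alternative") <- alternative
  out
}

cluster_rows <- function(zz, f, threshold, alternative) {
  lab <- if (alternative == "greater") {
    ifelse(zz > threshold, 1L, 0L)
  } else {
    ifelse(zz > threshold, 1L, ifelse(zz < -threshold, -1L, 0L))
  }
  r <- rle(lab)
  stop_i <- cumsum(r$lengths)
  start_i <- stop_i - r$lengths + 1L
  keep <- which(r$values != 0L)
  tibble::tibble(
    cluster = seq_along(keep),
    start_freq = f[start_i[keep]],
    end_freq = f[stop_i[keep]],
    n_freqs = r$lengths[keep],
    sign = r$values[keep],
    mass = vapply(keep, function(i) sum(abs(zz[start_i[i]:stop_i[i]])),
                  numeric(1))
  )
}

# max cluster mass of a z vector (fast path used inside the permutation loop)
max_mass <- function(zz, threshold, alternative) {
  if (alternative == "greater") {
    hit <- zz > threshold
    if (!any(hit)) return(0)
    r <- rle(hit)
    stop_i <- cumsum(r$lengths)
    m <- 0
    for (i in which(r$values)) {
      m <- max(m, sum(zz[(stop_i[i] - r$lengths[i] + 1L):stop_i[i]]))
    }
    m
  } else {
    max(max_mass(zz, threshold, "greater"),
        max_mass(-zz, threshold, "greater"))
  }
}

#' Maximum cluster-mass statistic
#'
#' The test statistic: the largest cluster mass, or 0 when no frequency
#' exceeds the cluster-forming threshold.
#'
#' @param clusters A `cmc_clusters` tibble.
#' @return A single number.
#' @export
max_cluster_stat <- function(clusters) {
  if (nrow(clusters) == 0) 0 else max(clusters$mass)
}

#' Randomly repartition two epoch sets
#'
#' Pools the epochs of both conditions and reassigns them uniformly at
#' random to two new sets of the original sizes; every epoch is used exactly
#' once. Draws from R's current RNG stream, so `set.seed()` makes the
#' partition reproducible.
#'
#' @param ep1,ep2 `cmc_epochs` with compatible channel layouts.
#' @return A list of two `cmc_epochs`.
#' @export
random_partition <- function(ep1, ep2) {
  pooled <- bind_epochs(ep1, ep2)
  n1 <- n_epochs(ep1)
  L <- n_epochs(pooled)
  idx <- sample.int(L)
  out1 <- subset_epochs(pooled, idx[seq_len(n1)])
  out2 <- subset_epochs(pooled, idx[(n1 + 1L):L])
  out1$condition <- ep1$condition
  out2$condition <- ep2$condition
  list(out1, out2)
}

#' Cluster-based permutation test of a coherence difference
#'
#' Tests whether the coherence of condition 1 exceeds that of condition 2
#' (default direction) within a frequency band. The observed statistic is
#' obtained by running the full sub-pipeline — multitaper coherence at the
#' analysis electrode(s), bias-corrected z-spectrum, supra-threshold
#' clustering, maximum cluster mass. The null distribution repeats the same
#' sub-pipeline on `n_perm` random partitions of the pooled 1-s segments,
#' and the Monte Carlo p-value is the proportion of partitions whose
#' statistic reaches the observed one, with the add-one correction
#' `p = (1 + #(null >= observed)) / (1 + n_perm)`.
#'
#' @param ep1,ep2 `cmc_epochs` for the two conditions.
#' @param eeg EEG electrode label(s): a single label used for both
#'   conditions, a length-2 vector giving each condition its own electrode
#'   (per-session beta-peak selection), or `NULL` to select each
#'   condition's beta-band peak electrode automatically.
#' @param emg EMG channel label.
#' @param n_perm Number of random partitions (default 5000). Values below
#'   100 trigger a warning.
#' @param threshold Cluster-forming threshold on z.
#' @param band Analysis band, Hz.
#' @param nw,k Multitaper parameters.
#' @param alternative `"greater"` (condition 1 > condition 2) or
#'   `"two.sided"`.
#' @param seed Optional seed for the partition stream.
#' @param selection_aware If `TRUE`, the beta-peak electrode is re-selected
#'   inside every permutation (guards against selection bias; off by
#'   default, matching a fixed-electrode analysis).
#' @param permute_unit `"epoch"` (pool 1-s segments; default) or `"trial"`
#'   (keep each trial's segments together, for robustness to within-trial
#'   autocorrelation).
#' @return An object of class `cmc_permutation`: observed statistic, null
#'   statistics, Monte Carlo p-value, observed clusters and z-spectrum, and
#'   a configuration echo. Use [tidy()] for the cluster table and
#'   [glance()] for a one-row summary.
#' @export
permutation_test <- function(ep1, ep2, eeg = NULL, emg = "EMG",
                             n_perm = 5000, threshold = 1.645,
                             band = c(15, 30), nw = 2, k = 3,
                             alternative = c("greater", "two.sided"),
                             seed = NULL, selection_aware = FALSE,
                             permute_unit = c("epoch", "trial")) {
  alternative <- match.arg(alternative)
  permute_unit <- match.arg(permute_unit)
  if (n_epochs(ep1) < 1 || n_epochs(ep2) < 1) {
    stop("pairing error: both epoch sets must be non-empty", call. = FALSE)
  }
  if (n_perm < 100) {
    warning("permutation_test: n_perm = ", n_perm,
            " is small; the Monte Carlo p-value will be coarse")
  }
  if (!is.null(seed)) set.seed(seed)

  # resolve analysis electrodes (per condition)
  if (is.null(eeg)) {
    e1 <- attr(band_topography(ep1, band = band, emg = emg, nw = nw, k = k),
               "peak_electrode")
    e2 <- attr(band_topography(ep2, band = band, emg = emg, nw = nw, k = k),
               "peak_electrode")
  } else if (length(eeg) == 1) {
    e1 <- e2 <- eeg
  } else {
    e1 <- eeg[1]; e2 <- eeg[2]
  }

  L1 <- n_epochs(ep1); L2 <- n_epochs(ep2)
  d1 <- 2 * k * L1; d2 <- 2 * k * L2
  if (d1 <= 2 || d2 <= 2) stop("dof error: degrees of freedom <= 2", call. = FALSE)

  # observed statistic from the actual labelling
  C1 <- coherence_spectrum(ep1, e1, emg, nw = nw, k = k)
  C2 <- coherence_spectrum(ep2, e2, emg, nw = nw, k = k)
  zobs <- z_difference(C1, C2)
  cl <- find_clusters(zobs, threshold, band, alternative)
  observed <- max_cluster_stat(cl)
  if (!is.finite(observed)) stop("numerical error: non-finite statistic",
                                 call. = FALSE)

  # pooled per-epoch multitaper building blocks at the analysis electrodes
  N <- dim(ep1$data)[2]
  tp <- make_tapers(N, nw, k)
  n_keep <- floor(N / 2) + 1L
  freqs <- (seq_len(n_keep) - 1) * ep1$fs / N
  sel <- which(check_band(freqs, band))

  chans <- if (selection_aware) {
    ep1$labels[ep1$kinds == "EEG"]
  } else unique(c(e1, e2))

  pool_blocks <- function(label) {
    x <- cbind(epoch_channel(ep1, label), epoch_channel(ep2, label))
    tapered_fft(x, tp, n_keep)[sel, , , drop = FALSE]
  }
  Y <- pool_blocks(emg)
  pyy <- rowSums(Mod(Y)^2, dims = 2)            # band-freq x epochs
  blocks <- lapply(chans, function(ch) {
    X <- pool_blocks(ch)
    list(pxy = rowSums(X * Conj(Y), dims = 2),
         pxx = rowSums(Mod(X)^2, dims = 2))
  })
  names(blocks) <- chans

  L <- L1 + L2
  # random partitions as an epochs x n_perm indicator matrix for condition 1
  if (permute_unit == "trial") {
    tr <- c(paste0("a", ep1$provenance$trial), paste0("b", ep2$provenance$trial))
    utr <- unique(tr)
    per_tr <- as.integer(table(factor(tr, levels = utr)))
    n_tr1 <- sum(tr %in% utr[seq_len(length(unique(tr[seq_len(L1)])))])
    I1 <- matrix(0, L, n_perm)
    for (b in seq_len(n_perm)) {
      ord <- sample(utr)
      csum <- cumsum(per_tr[match(ord, utr)])
      take <- ord[seq_len(which.min(abs(csum - L1)))]
      I1[tr %in% take, b] <- 1
    }
    n1_eff <- colSums(I1)
  } else {
    I1 <- matrix(0, L, n_perm)
    for (b in seq_len(n_perm)) I1[sample.int(L, L1), b] <- 1
    n1_eff <- rep(L1, n_perm)
  }
  n2_eff <- L - n1_eff

  perm_coh <- function(bl) {
    tot_xy <- rowSums(bl$pxy)
    tot_xx <- rowSums(bl$pxx)
    tot_yy <- rowSums(pyy)
    S1xy <- bl$pxy %*% I1
    S1xx <- bl$pxx %*% I1
    S1yy <- pyy %*% I1
    C1p <- Mod(S1xy) / sqrt(Re(S1xx) * Re(S1yy))
    C2p <- Mod(tot_xy - S1xy) / sqrt(Re(tot_xx - S1xx) * Re(tot_yy - S1yy))
    list(C1 = C1p, C2 = C2p)
  }

  nb <- length(sel)
  if (!selection_aware) {
    pc1 <- perm_coh(blocks[[e1]])
    pc2 <- if (e2 == e1) pc1 else perm_coh(blocks[[e2]])
    C1mat <- pc1$C1
    C2mat <- pc2$C2
  } else {
    # re-select each pseudo-condition's band-peak electrode per permutation
    all_pc <- lapply(blocks, perm_coh)
    bm1 <- vapply(all_pc, function(p) colMeans(p$C1), numeric(n_perm))
    bm2 <- vapply(all_pc, function(p) colMeans(p$C2), numeric(n_perm))
    pick1 <- max.col(bm1, ties.method = "first")
    pick2 <- max.col(bm2, ties.method = "first")
    C1mat <- matrix(0, nb, n_perm)
    C2mat <- matrix(0, nb, n_perm)
    for (b in seq_len(n_perm)) {
      C1mat[, b] <- all_pc[[pick1[b]]]$C1[, b]
      C2mat[, b] <- all_pc[[pick2[b]]]$C2[, b]
    }
  }

  n1v <- 1 / (2 * k * n1_eff - 2)
  n2v <- 1 / (2 * k * n2_eff - 2)
  null_stats <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    zb <- z_values(C1mat[, b], C2mat[, b], n1v[b], n2v[b])
    null_stats[b] <- max_mass(zb, threshold, alternative)
  }
  p_mc <- (1 + sum(null_stats >= observed)) / (1 + n_perm)

  structure(
    list(observed_stat = observed, null_stats = null_stats, p_mc = p_mc,
         n_permutations = n_perm, clusters = cl, z = zobs,
         spectra = list(C1, C2),
         electrodes = c(e1, e2), d = c(d1, d2), L = c(L1, L2),
         config = list(emg = emg, n_perm = n_perm, threshold = threshold,
                       band = band, nw = nw, k = k,
                       alternative = alternative, seed = seed,
                       selection_aware = selection_aware,
                       permute_unit = permute_unit)),
    class = "cmc_permutation"
  )
}

#' @export
print.cmc_permutation <- function(x, ...) {
  cat("<cmc_permutation> cluster-based permutation test\n")
  cat("  electrodes: ", paste(unique(x$electrodes), collapse = " / "),
      "  (L = ", x$L[1], " / ", x$L[2], " epochs)\n", sep = "")
  cat("  band ", x$config$band[1], "-", x$config$band[2], " Hz, ",
      x$n_permutations, " partitions, ", x$config$alternative, "\n", sep = "")
  cat("  observed statistic = ", format(x$observed_stat, digits = 4),
      ", Monte Carlo p = ", format(x$p_mc, digits = 4), "\n", sep = "")
  invisible(x)
}
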