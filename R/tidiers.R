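#' Tidy a permutation test: one row per observed cluster
#'
#' @param x A `cmc_permutation`.
#' @param ... Unused.
#' @return A tibble with the cluster table (`start_freq`, `end_freq`,
#'   `n_freqs`, `sign`, `mass`).
#' @method tidy cmc_permutation
#' @export
tidy.cmc_permutation <- function(x, ...) {
  tibble::as_tibble(x$clusters)
}

#' One-row summary of a permutation test
#'
#' @param x A `cmc_permutation`.
#' @param ... Unused.
#' @return A tibble with `observed_stat`, `p_mc`, `n_permutations`,
#'   `threshold`, `band_low`, `band_high`, `alternative`, `electrode_1`,
#'   `electrode_2`, `d1`, `d2`.
#' @method glance cmc_permutation
#' @export
glance.cmc_permutation <- function(x, ...) {
  tibble::tibble(
    observed_stat = x$observed_stat,
    p_mc = x$p_mc,
    n_permutations = x$n_permutations,
    threshold = x$config$threshold,
    band_low = x$config$band[1],
    band_high = x$config$band[2],
    alternative = x$config$alternative,
    electrode_1 = x$electrodes[1],
    electrode_2 = x$electrodes[2],
    d1 = x$d[1],
    d2 = x$d[2]
  )
}

#' Tidy an ICA decomposition: one row per component
#'
#' @param x A `cmc_ica`.
#' @param ... Unused.
#' @return A tibble with `component` and `explained` (variance accounted
#'   for by each component's back-projection).
#' @method tidy cmc_ica
#' @export
tidy.cmc_ica <- function(x, ...) {
  tibble::tibble(component = seq_len(x$n_components), explained = x$explained)
}
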