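#' Electrode montage on the unit sphere
#'
#' A montage is a tibble with one row per electrode and columns `label`,
#' `x`, `y`, `z`, where positions lie on the unit sphere (head modelled as a
#' sphere of unit radius). The coordinate convention is RAS-like: `x` points
#' to the subject's right, `y` anterior, `z` up. The recording reference
#' position (Cz, the vertex) is carried as the `reference` attribute; it need
#' not be a measurement electrode.
#'
#' @param n Number of electrodes, at least 8 (spherical-spline fitting needs
#'   a spatial spread).
#' @details
#' `make_montage()` places `n` quasi-uniform points on the upper portion of
#' the sphere (a golden-angle / Fibonacci spiral restricted to `z >= -0.2`,
#' covering scalp down to just below the equator, as an idealisation of a
#' 128-channel geodesic net). Labels are `"E001"`, `"E002"`, ... in spiral
#' order from vertex to rim. The construction is deterministic.
#' @return A tibble of class `cmc_montage` with columns `label`, `x`, `y`, `z`.
#' @examples
#' mont <- make_montage(32)
#' head(mont)
#' @export
make_montage <- function(n = 128) {
  if (!is.numeric(n) || length(n) != 1 || n < 8) {
    stop("montage error: need at least 8 electrodes, got ", n, call. = FALSE)
  }
  n <- as.integer(n)
  golden <- pi * (3 - sqrt(5))
  i <- seq_len(n)
  # z descends from vertex (1) to the rim (-0.2)
  z <- 1 - (i - 0.5) / n * 1.2
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- golden * i
  out <- tibble::tibble(
    label = sprintf("E%03d", i),
    x = r * cos(phi),
    y = r * sin(phi),
    z = z
  )
  new_montage(out, reference = "Cz")
}

new_montage <- function(df, reference = "Cz") {
  df <- tibble::as_tibble(df)
  class(df) <- c("cmc_montage", class(df))
  attr(df, "reference") <- reference
  validate_montage(df)
  df
}

validate_montage <- function(mont) {
  stopifnot(all(c("label", "x", "y", "z") %in% names(mont)))
  if (anyDuplicated(mont$label)) {
    stop("montage error: duplicate electrode labels: ",
         paste(unique(mont$label[duplicated(mont$label)]), collapse = ", "),
         call. = FALSE)
  }
  if (nrow(mont) < 8) {
    stop("montage error: need at least 8 electrodes, got ", nrow(mont),
         call. = FALSE)
  }
  nrm <- sqrt(mont$x^2 + mont$y^2 + mont$z^2)
  if (any(abs(nrm - 1) > 1e-9)) {
    stop("montage error: positions must lie on the unit sphere", call. = FALSE)
  }
  invisible(mont)
}

montage_positions <- function(mont) {
  as.matrix(mont[, c("x", "y", "z")])
}

#' Great-circle distances between montage electrodes
#'
#' @param mont A `cmc_montage`.
#' @param from Label of the electrode distances are measured from. If `NULL`,
#'   the full pairwise distance matrix (radians) is returned.
#' @return A named numeric vector (or square matrix) of angles in radians.
#' @export
montage_distances <- function(mont, from = NULL) {
  pos <- montage_positions(mont)
  if (is.null(from)) {
    ct <- tcrossprod(pos)
    d <- acos(pmin(pmax(ct, -1), 1))
    dimnames(d) <- list(mont$label, mont$label)
    return(d)
  }
  idx <- match(from, mont$label)
  if (is.na(idx)) stop("montage error: no electrode labelled ", from, call. = FALSE)
  ct <- as.vector(pos %*% pos[idx, ])
  stats::setNames(acos(pmin(1, pmax(-1, ct))), mont$label)
}

#' Read an electrode position file
#'
#' Reads a plain-text, whitespace-delimited position file with one
#' `label x y z` record per line (`.sfp`-style). Positions are renormalised
#' onto the unit sphere; the line order is preserved.
#'
#' @param path Path to the position file.
#' @return A `cmc_montage` tibble.
#' @export
read_montage <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "\\s+")
  nt <- lengths(toks)
  if (any(nt != 4)) {
    bad <- which(nt != 4)[1]
    stop("montage parse error at line ", bad, ": expected 4 fields, got ",
         nt[bad], call. = FALSE)
  }
  m <- do.call(rbind, lapply(toks, function(t) as.numeric(t[2:4])))
  if (anyNA(m)) stop("montage parse error: non-numeric coordinate", call. = FALSE)
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm == 0)) stop("montage error: zero-length position vector", call. = FALSE)
  m <- m / nrm
  new_montage(tibble::tibble(
    label = vapply(toks, `[[`, "", 1),
    x = m[, 1], y = m[, 2], z = m[, 3]
  ))
}

#' Write an electrode position file
#'
#' Inverse of [read_montage()]: writes one `label x y z` line per electrode
#' with full double precision.
#'
#' @param mont A `cmc_montage`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_montage <- function(mont, path) {
  validate_montage(mont)
  writeLines(sprintf("%s %.17g %.17g %.17g", mont$label, mont$x, mont$y, mont$z),
             path)
  invisible(path)
}

#' @export
print.cmc_montage <- function(x, ...) {
  cat("<cmc_montage> ", nrow(x), " electrodes, reference ",
      attr(x, "reference") %||% "?", "\n", sep = "")
  NextMethod()
}
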