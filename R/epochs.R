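#' Segment the contraction period of each trial into fixed-length epochs
#'
#' Within every trial the first `skip_s` seconds (the interval allotted for
#' reaching the target force) are skipped; the remainder of the half-open
#' trial window is tiled left-to-right with non-overlapping `epoch_s`-second
#' windows, and any partial trailing window is discarded. An 11-s trial with
#' a 2-s skip and 1-s epochs therefore yields exactly 9 epochs.
#'
#' @param rec A `cmc_recording` whose events define the trials.
#' @param epoch_s Epoch length in seconds (`epoch_s * fs` must be integral).
#' @param skip_s Seconds skipped at the start of each trial.
#' @param condition Condition label; defaults to `"<side>_s<session>"` from
#'   the recording metadata when available.
#' @return A `cmc_epochs` object: a channels x samples x epochs array plus
#'   channel labels/kinds, sampling rate, condition label and a provenance
#'   table recording the (run, trial) of every epoch.
#' @export
segment_epochs <- function(rec, epoch_s = 1, skip_s = 2, condition = NULL) {
  validate_recording(rec)
  N <- epoch_s * rec$fs
  if (abs(N - round(N)) > 1e-9) {
    stop("segmentation error: epoch_s * fs must be an integer number of samples",
         call. = FALSE)
  }
  N <- as.integer(round(N))
  trials <- recording_trials(rec)
  if (nrow(trials) == 0) {
    stop("empty-set error: recording has no trial events", call. = FALSE)
  }
  skip <- as.integer(round(skip_s * rec$fs))
  ntr_run <- rec$meta$n_trials_per_run %||% nrow(trials)

  idx_list <- list()
  prov <- list()
  for (i in seq_len(nrow(trials))) {
    first <- trials$start[i] + skip
    n_ep <- floor((trials$end[i] - first) / N)
    if (n_ep <= 0) {
      message("segment_epochs: trial ", i, " shorter than skip + epoch; skipped")
      next
    }
    for (k in seq_len(n_ep)) {
      idx_list[[length(idx_list) + 1L]] <- first + (k - 1L) * N
      prov[[length(prov) + 1L]] <- c(run = ceiling(i / ntr_run), trial = i)
    }
  }
  if (!length(idx_list)) {
    stop("empty-set error: no trial long enough to contribute an epoch",
         call. = FALSE)
  }
  starts <- unlist(idx_list)
  n_ep <- length(starts)
  data <- array(0, dim = c(nrow(rec$data), N, n_ep))
  for (e in seq_len(n_ep)) {
    data[, , e] <- rec$data[, (starts[e] + 1L):(starts[e] + N), drop = FALSE]
  }
  pv <- do.call(rbind, prov)
  condition <- condition %||%
    if (!is.null(rec$meta$side)) {
      paste0(rec$meta$side, "_s", rec$meta$session %||% 1)
    } else "cond"
  structure(
    list(data = data, fs = rec$fs, labels = rec$labels, kinds = rec$kinds,
         condition = condition,
         provenance = tibble::tibble(epoch = seq_len(n_ep),
                                     run = pv[, "run"], trial = pv[, "trial"]),
         meta = rec$meta),
    class = "cmc_epochs"
  )
}

#' @export
print.cmc_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat("<cmc_epochs> ", d[3], " epochs x ", d[1], " channels x ", d[2],
      " samples (", x$condition, ")\n", sep = "")
  invisible(x)
}

n_epochs <- function(ep) dim(ep$data)[3]

#' Extract one channel of an epoch set
#'
#' @param ep A `cmc_epochs`.
#' @param label Channel label.
#' @return A samples x epochs numeric matrix.
#' @export
epoch_channel <- function(ep, label) {
  idx <- match(label, ep$labels)
  if (is.na(idx)) {
    stop("pairing error: no channel labelled '", label, "'", call. = FALSE)
  }
  m <- ep$data[idx, , , drop = TRUE]
  if (is.null(dim(m))) m <- matrix(m, ncol = 1)  # single epoch
  m
}

subset_epochs <- function(ep, idx) {
  out <- ep
  out$data <- ep$data[, , idx, drop = FALSE]
  out$provenance <- ep$provenance[idx, , drop = FALSE]
  out
}

bind_epochs <- function(ep1, ep2) {
  if (!identical(ep1$labels, ep2$labels) || !identical(ep1$kinds, ep2$kinds) ||
      ep1$fs != ep2$fs || dim(ep1$data)[2] != dim(ep2$data)[2]) {
    stop("pairing error: epoch sets have incompatible channel layouts",
         call. = FALSE)
  }
  out <- ep1
  out$data <- array(c(ep1$data, ep2$data),
                    dim = c(dim(ep1$data)[1], dim(ep1$data)[2],
                            n_epochs(ep1) + n_epochs(ep2)))
  out$provenance <- dplyr::bind_rows(ep1$provenance, ep2$provenance)
  out$provenance$epoch <- seq_len(nrow(out$provenance))
  out$condition <- paste(ep1$condition, ep2$condition, sep = "+")
  out
}
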