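#' Multichannel recording container
#'
#' A `cmc_recording` holds a channels x samples numeric matrix together with
#' the sampling rate, per-channel labels and kinds (EEG / EMG / FORCE), trial
#' event markers and free-form metadata. EEG and EMG are in microvolts, force
#' in newtons. Sample indexing is 0-based in the `events` table (an event at
#' sample 0 is the first sample) and trial windows `[trial_start, trial_end)`
#' are half-open.
#'
#' @param data Numeric matrix, channels x samples.
#' @param fs Sampling rate in Hz.
#' @param labels Character vector of channel labels (one per row of `data`).
#' @param kinds Character vector of channel kinds, each one of `"EEG"`,
#'   `"EMG"`, `"FORCE"`. If `NULL`, kinds are inferred from labels via
#'   [infer_channel_kinds()].
#' @param events A data frame with columns `sample` (0-based integer) and
#'   `code` (`"trial_start"` / `"trial_end"`), or `NULL` for none.
#' @param meta Named list of provenance (e.g. `side`, `session`, `montage`).
#' @return An object of class `cmc_recording`.
#' @export
new_recording <- function(data, fs, labels, kinds = NULL, events = NULL,
                          meta = list()) {
  data <- as.matrix(data)
  if (is.null(kinds)) kinds <- infer_channel_kinds(labels)
  if (is.null(events)) {
    events <- tibble::tibble(sample = integer(), code = character())
  }
  events <- tibble::as_tibble(events)
  rec <- structure(
    list(data = data, fs = fs, labels = labels, kinds = kinds,
         events = events, meta = meta),
    class = "cmc_recording"
  )
  validate_recording(rec)
  rec
}

validate_recording <- function(rec) {
  stopifnot(inherits(rec, "cmc_recording"))
  if (!is.numeric(rec$fs) || length(rec$fs) != 1 || rec$fs <= 0) {
    stop("recording error: sampling rate must be a positive scalar", call. = FALSE)
  }
  if (nrow(rec$data) != length(rec$labels)) {
    stop("recording error: data has ", nrow(rec$data),
         " rows but ", length(rec$labels), " labels", call. = FALSE)
  }
  if (length(rec$kinds) != length(rec$labels)) {
    stop("recording error: kinds/labels length mismatch", call. = FALSE)
  }
  if (!all(rec$kinds %in% c("EEG", "EMG", "FORCE"))) {
    stop("recording error: unknown channel kind: ",
         paste(setdiff(rec$kinds, c("EEG", "EMG", "FORCE")), collapse = ", "),
         call. = FALSE)
  }
  ev <- rec$events
  if (nrow(ev)) {
    if (is.unsorted(ev$sample)) {
      stop("recording error: events must be sorted by sample index", call. = FALSE)
    }
    starts <- ev$sample[ev$code == "trial_start"]
    ends <- ev$sample[ev$code == "trial_end"]
    if (length(starts) != length(ends) || any(ends <= starts)) {
      stop("recording error: every trial_start needs a later trial_end",
           call. = FALSE)
    }
  }
  invisible(rec)
}

#' Infer channel kinds from labels
#'
#' Labels beginning with `"EMG"` map to EMG, `"FORCE"` to FORCE and
#' `"E"`/`"EEG"` to EEG; anything else is a classification error unless an
#' explicit override is supplied to the caller.
#'
#' @param labels Character vector of channel labels.
#' @param overrides Optional named character vector mapping label to kind.
#' @return Character vector of kinds.
#' @export
infer_channel_kinds <- function(labels, overrides = NULL) {
  vapply(labels, function(lb) {
    if (!is.null(overrides) && lb %in% names(overrides)) return(overrides[[lb]])
    if (grepl("^EMG", lb, ignore.case = TRUE)) return("EMG")
    if (grepl("^FORCE", lb, ignore.case = TRUE)) return("FORCE")
    if (grepl("^(E|EEG)", lb, ignore.case = TRUE)) return("EEG")
    stop("channel classification error: cannot infer kind for label '", lb,
         "'; supply channel_kinds", call. = FALSE)
  }, character(1), USE.NAMES = FALSE)
}

#' @export
print.cmc_recording <- function(x, ...) {
  dur <- ncol(x$data) / x$fs
  cat("<cmc_recording> ", nrow(x$data), " channels x ", ncol(x$data),
      " samples (", format(dur, digits = 4), " s @ ", x$fs, " Hz)\n", sep = "")
  tab <- table(x$kinds)
  cat("  channels: ", paste(names(tab), tab, sep = ":", collapse = "  "), "\n", sep = "")
  cat("  events:   ", nrow(x$events), "\n", sep = "")
  if (length(x$meta)) {
    keys <- setdiff(names(x$meta), "montage")
    if (length(keys)) {
      cat("  meta:     ",
          paste(keys, vapply(x$meta[keys], function(v) paste(format(v), collapse = ","), ""),
                sep = "=", collapse = "  "), "\n", sep = "")
    }
  }
  invisible(x)
}

#' Trials of a recording
#'
#' Pairs each `trial_start` event with its `trial_end` and returns the
#' half-open sample windows.
#'
#' @param rec A `cmc_recording`.
#' @return A tibble with columns `trial`, `start`, `end` (0-based samples).
#' @export
recording_trials <- function(rec) {
  ev <- rec$events
  starts <- ev$sample[ev$code == "trial_start"]
  ends <- ev$sample[ev$code == "trial_end"]
  tibble::tibble(trial = seq_along(starts), start = starts, end = ends)
}

#' Subset a recording to selected channels
#'
#' Keeps only the named channels (in the given order), preserving events and
#' metadata. Useful for restricting long sessions to an analysis pair before
#' segmentation.
#'
#' @param rec A `cmc_recording`.
#' @param labels Channel labels to keep.
#' @return A `cmc_recording`.
#' @export
select_channels <- function(rec, labels) {
  idx <- channel_index(rec, labels)
  out <- rec
  out$data <- rec$data[idx, , drop = FALSE]
  out$labels <- rec$labels[idx]
  out$kinds <- rec$kinds[idx]
  out
}

channel_index <- function(rec, label) {
  idx <- match(label, rec$labels)
  if (anyNA(idx)) {
    stop("recording error: no channel labelled ",
         paste(label[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  idx
}
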