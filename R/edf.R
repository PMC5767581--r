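# EDF/EDF+ reader and writer.
#
# 16-bit EDF with one data record per second; trial events are stored as
# EDF+ time-stamped annotation lists (TALs) in an "EDF Annotations" signal.
# Physical min/max are set per channel from the data extrema with 5%
# headroom, which keeps the quantisation step far below the noise floor.

TAL_SEP <- as.raw(0x14)   # annotation field separator
TAL_DUR <- as.raw(0x15)   # duration marker
TAL_END <- as.raw(0x00)

pad_field <- function(x, width) {
  s <- as.character(x)
  if (nchar(s, type = "bytes") > width) s <- substr(s, 1, width)
  formatC(s, width = -width)
}

#' Write a recording to an EDF+ file
#'
#' Writes one EDF signal per channel (16-bit, one-second data records) plus
#' an annotation signal carrying the trial events with onsets in seconds.
#' [read_recording()] inverts it up to 16-bit quantisation of the sample
#' values. Recordings whose duration is not a whole number of seconds are
#' zero-padded to the next full record; the padding is not marked.
#'
#' @param rec A `cmc_recording` with finite sample values and integer `fs`.
#' @param path Output file path (directory must exist).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  validate_recording(rec)
  if (!all(is.finite(rec$data))) {
    stop("value error: non-finite samples cannot be written to EDF", call. = FALSE)
  }
  if (rec$fs != round(rec$fs)) {
    stop("value error: EDF writer requires an integer sampling rate", call. = FALSE)
  }
  if (!dir.exists(dirname(path))) {
    stop("I/O error: directory does not exist: ", dirname(path), call. = FALSE)
  }
  fs <- as.integer(rec$fs)
  nch <- nrow(rec$data)
  nsamp <- ncol(rec$data)
  n_rec <- max(1L, as.integer(ceiling(nsamp / fs)))

  # physical ranges with 5% headroom; degenerate (constant) channels get +/-1
  pmin <- apply(rec$data, 1, min)
  pmax <- apply(rec$data, 1, max)
  span <- pmax - pmin
  mid <- (pmax + pmin) / 2
  half <- ifelse(span > 0, span / 2 * 1.05, 1)
  pmin <- mid - half
  pmax <- mid + half

  # annotation TALs per record
  ann <- build_annotation_records(rec$events, fs, n_rec)
  ann_spr <- max(16L, as.integer(ceiling(max(lengths(ann)) / 2)))

  units <- c(EEG = "uV", EMG = "uV", FORCE = "N")[rec$kinds]

  con <- file(path, "wb")
  on.exit(close(con))
  ns_total <- nch + 1L
  hdr <- paste0(
    pad_field("0", 8),
    pad_field("X X X X", 80),
    pad_field(paste("Startdate 01-JAN-2026 cmcoh", recording_id_string(rec$meta)), 80),
    "01.01.26", "00.00.00",
    pad_field((ns_total + 1L) * 256L, 8),
    pad_field("EDF+C", 44),
    pad_field(n_rec, 8),
    pad_field(1, 8),
    pad_field(ns_total, 4)
  )
  writeChar(hdr, con, eos = NULL)
  labs <- c(rec$labels, "EDF Annotations")
  sig_field <- function(vals, width) {
    writeChar(paste(vapply(vals, pad_field, "", width = width), collapse = ""),
              con, eos = NULL)
  }
  sig_field(labs, 16)
  sig_field(rep("", ns_total), 80)                      # transducer
  sig_field(c(units, ""), 8)                            # physical dimension
  sig_field(c(sprintf("%.8g", pmin), "-32768"), 8)
  sig_field(c(sprintf("%.8g", pmax), "32767"), 8)
  sig_field(rep("-32768", ns_total), 8)
  sig_field(rep("32767", ns_total), 8)
  sig_field(rep("", ns_total), 80)                      # prefilter
  sig_field(c(rep(fs, nch), ann_spr), 8)
  sig_field(rep("", ns_total), 32)

  scale <- (pmax - pmin) / 65535
  for (r in seq_len(n_rec)) {
    s0 <- (r - 1L) * fs
    take <- seq.int(s0 + 1L, min(s0 + fs, nsamp))
    for (ch in seq_len(nch)) {
      seg <- numeric(fs)
      seg[seq_along(take)] <- rec$data[ch, take]
      dig <- as.integer(round((seg - pmin[ch]) / scale[ch]) - 32768)
      dig <- pmin(32767L, pmax(-32768L, dig))
      writeBin(dig, con, size = 2, endian = "little")
    }
    tal <- ann[[r]]
    buf <- raw(ann_spr * 2L)
    buf[seq_along(tal)] <- tal
    writeBin(buf, con)
  }
  invisible(path)
}

recording_id_string <- function(meta) {
  bits <- character()
  if (!is.null(meta$side)) bits <- c(bits, paste0("side=", meta$side))
  if (!is.null(meta$session)) bits <- c(bits, paste0("session=", meta$session))
  paste(bits, collapse = " ")
}

build_annotation_records <- function(events, fs, n_rec) {
  lapply(seq_len(n_rec), function(r) {
    t0 <- r - 1L
    # record-keeping TAL required by EDF+
    tal <- c(charToRaw(sprintf("+%d", t0)), TAL_SEP, TAL_SEP, TAL_END)
    if (nrow(events)) {
      in_rec <- which(events$sample >= t0 * fs & events$sample < r * fs)
      for (i in in_rec) {
        onset <- events$sample[i] / fs
        tal <- c(tal,
                 charToRaw(sprintf("+%.7f", onset)), TAL_SEP,
                 charToRaw(events$code[i]), TAL_SEP, TAL_END)
      }
    }
    tal
  })
}

#' Read a recording from an EDF/EDF+ file
#'
#' Reads all ordinary signals into a channels x samples matrix and decodes
#' EDF+ annotations named `"trial_start"`/`"trial_end"` into the event
#' table. Channel kinds are inferred from labels (prefix `E`/`EEG` is EEG,
#' `EMG` is EMG, `FORCE` is FORCE) unless overridden.
#'
#' @param path Path to an EDF file.
#' @param channel_kinds Optional named character vector mapping channel
#'   label to kind, overriding label-based inference.
#' @return A `cmc_recording`.
#' @export
read_recording <- function(path, channel_kinds = NULL) {
  if (!file.exists(path)) stop("I/O error: no such file: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  rd_field <- function(width, n = 1) {
    vapply(seq_len(n), function(i) {
      trimws(rawToChar(readBin(con, "raw", width)))
    }, "")
  }
  rd_num <- function(width, n = 1, field) {
    v <- suppressWarnings(as.numeric(rd_field(width, n)))
    if (anyNA(v)) {
      stop("EDF format error: unparsable header field '", field, "'", call. = FALSE)
    }
    v
  }
  rd_field(8)                                  # version
  rd_field(80); rd_field(80)                   # patient / recording id
  meta_str <- character(0)
  seek(con, 88)
  rec_id <- rd_field(80)
  rd_field(8); rd_field(8)                     # date, time
  hdr_bytes <- rd_num(8, field = "number of bytes in header")
  rd_field(44)                                 # reserved
  n_rec <- rd_num(8, field = "number of data records")
  rec_dur <- rd_num(8, field = "duration of a data record")
  ns <- as.integer(rd_num(4, field = "number of signals"))
  if (ns < 1) stop("EDF format error: number of signals < 1", call. = FALSE)

  labels <- rd_field(16, ns)
  rd_field(80, ns)
  units <- rd_field(8, ns)
  phys_min <- rd_num(8, ns, "physical minimum")
  phys_max <- rd_num(8, ns, "physical maximum")
  dig_min <- rd_num(8, ns, "digital minimum")
  dig_max <- rd_num(8, ns, "digital maximum")
  rd_field(80, ns)
  spr <- as.integer(rd_num(8, ns, "samples per record"))
  rd_field(32, ns)

  rec_bytes <- sum(spr) * 2L
  expected <- hdr_bytes + n_rec * rec_bytes
  actual <- file.size(path)
  if (actual < expected) {
    stop("EDF format error: header field 'number of data records' promises ",
         n_rec, " records (", expected, " bytes) but file has ", actual,
         " bytes", call. = FALSE)
  }
  seek(con, hdr_bytes)
  payload <- readBin(con, "raw", n_rec * rec_bytes)

  is_ann <- labels == "EDF Annotations"
  sig_idx <- which(!is_ann)
  # byte offset of each signal within a record
  off <- c(0L, cumsum(spr * 2L))
  events <- tibble::tibble(sample = integer(), code = character())

  data <- NULL
  fs <- NULL
  if (length(sig_idx)) {
    fs <- spr[sig_idx[1]] / rec_dur
    if (any(spr[sig_idx] != spr[sig_idx[1]])) {
      stop("EDF format error: heterogeneous sampling rates across signals",
           call. = FALSE)
    }
    data <- matrix(0, length(sig_idx), n_rec * spr[sig_idx[1]])
  }
  for (r in seq_len(n_rec)) {
    base <- (r - 1L) * rec_bytes
    for (j in seq_along(sig_idx)) {
      s <- sig_idx[j]
      raw_seg <- payload[(base + off[s] + 1L):(base + off[s + 1L])]
      dig <- readBin(raw_seg, "integer", n = spr[s], size = 2, signed = TRUE,
                     endian = "little")
      phys <- (dig - dig_min[s]) * (phys_max[s] - phys_min[s]) /
        (dig_max[s] - dig_min[s]) + phys_min[s]
      data[j, ((r - 1L) * spr[s] + 1L):(r * spr[s])] <- phys
    }
    for (s in which(is_ann)) {
      raw_seg <- payload[(base + off[s] + 1L):(base + off[s + 1L])]
      events <- rbind(events, parse_tals(raw_seg, fs %||% 1))
    }
  }
  if (is.null(data)) stop("EDF format error: no ordinary signals", call. = FALSE)
  if (nrow(events)) {
    events <- events[order(events$sample), , drop = FALSE]
  }
  meta <- parse_recording_id(rec_id)
  new_recording(
    data, fs = fs, labels = labels[sig_idx],
    kinds = infer_channel_kinds(labels[sig_idx], overrides = channel_kinds),
    events = events, meta = meta
  )
}

parse_tals <- function(raw_seg, fs) {
  out <- tibble::tibble(sample = integer(), code = character())
  # TALs are NUL-terminated; split on 0x00
  ends <- which(raw_seg == TAL_END)
  start <- 1L
  for (e in ends) {
    if (e > start) {
      tal <- raw_seg[start:(e - 1L)]
      fields <- split_raw(tal, TAL_SEP)
      if (length(fields) >= 2) {
        onset_str <- strsplit(fields[[1]], rawToChar(TAL_DUR))[[1]][1]
        onset <- suppressWarnings(as.numeric(onset_str))
        for (txt in fields[-1]) {
          if (txt %in% c("trial_start", "trial_end") && !is.na(onset)) {
            out <- rbind(out, tibble::tibble(sample = as.integer(round(onset * fs)),
                                             code = txt))
          }
        }
      }
    }
    start <- e + 1L
  }
  out
}

split_raw <- function(r, sep) {
  idx <- which(r == sep)
  starts <- c(1L, idx + 1L)
  stops <- c(idx - 1L, length(r))
  lapply(seq_along(starts), function(i) {
    if (stops[i] < starts[i]) "" else rawToChar(r[starts[i]:stops[i]])
  })
}

parse_recording_id <- function(id) {
  meta <- list()
  m <- regmatches(id, regexec("side=(\\S+)", id))[[1]]
  if (length(m) == 2) meta$side <- m[2]
  m <- regmatches(id, regexec("session=(\\S+)", id))[[1]]
  if (length(m) == 2) meta$session <- as.integer(m[2])
  meta
}
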