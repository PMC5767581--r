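# EDF round-trips and tabular result output.

make_test_recording <- function(n_s = 41, fs = 200, seed = 4) {
  set.seed(seed)
  n <- n_s * fs
  data <- rbind(
    sin(2 * pi * 20 * (0:(n - 1)) / fs) * 50,
    stats::rnorm(n, sd = 10),
    stats::rnorm(n, sd = 10),
    stats::rnorm(n, sd = 0.5)
  )
  # two trials with [start, end) windows
  ev <- tibble::tibble(
    sample = as.integer(c(0, 11 * fs, 13 * fs, 24 * fs)),
    code = c("trial_start", "trial_end", "trial_start", "trial_end")
  )
  new_recording(data, fs = fs, labels = c("E001", "E002", "E003", "EMG"),
                events = ev, meta = list(side = "affected", session = 2L))
}

test_that("EDF write/read round-trips channels, events and metadata", {
  rec <- make_test_recording()
  f <- withr::local_tempfile(fileext = ".edf")
  write_recording(rec, f)
  back <- read_recording(f)

  expect_identical(back$labels, rec$labels)
  expect_identical(back$kinds, c("EEG", "EEG", "EEG", "EMG"))
  expect_equal(back$fs, rec$fs)
  expect_identical(back$events$sample, rec$events$sample)
  expect_identical(back$events$code, rec$events$code)
  expect_identical(back$meta$side, "affected")
  expect_identical(back$meta$session, 2L)

  # sample values within one 16-bit quantisation step per channel
  span <- apply(rec$data, 1, function(r) diff(range(r))) * 1.05
  step <- span / 65535
  for (ch in 1:4) {
    expect_lt(max(abs(back$data[ch, seq_len(ncol(rec$data))] - rec$data[ch, ])),
              step[ch] * 1.01)
  }
})

test_that("zero-valued channels decode to zero within quantisation", {
  rec <- new_recording(matrix(0, 2, 400), fs = 100,
                       labels = c("E001", "EMG"))
  f <- withr::local_tempfile(fileext = ".edf")
  write_recording(rec, f)
  back <- read_recording(f)
  expect_lt(max(abs(back$data)), 2 / 65535 * 1.01)
})

test_that("channel kinds follow the label rule with overrides available", {
  expect_identical(infer_channel_kinds(c("E01", "EEG2", "E03", "EMG")),
                   c("EEG", "EEG", "EEG", "EMG"))
  expect_error(infer_channel_kinds(c("E01", "AUX")), "classification error")
  expect_identical(infer_channel_kinds(c("E01", "AUX"),
                                       overrides = c(AUX = "FORCE")),
                   c("EEG", "FORCE"))
})

test_that("EDF reader rejects truncated files naming the header field", {
  rec <- make_test_recording(n_s = 10)
  f <- withr::local_tempfile(fileext = ".edf")
  write_recording(rec, f)
  full <- readBin(f, "raw", file.size(f))
  writeBin(full[seq_len(length(full) - 4000)], f)
  expect_error(read_recording(f), "number of data records")
})

test_that("EDF writer validates input", {
  rec <- make_test_recording(n_s = 10)
  rec$data[1, 5] <- NaN
  f <- withr::local_tempfile(fileext = ".edf")
  expect_error(write_recording(rec, f), "value error")
  rec2 <- make_test_recording(n_s = 10)
  expect_error(write_recording(rec2, file.path(tempdir(), "no_dir_here",
                                               "x.edf")),
               "I/O error")
})

test_that("result tables serialise deterministically and re-parse exactly", {
  tab <- result_table(key = "coh.E042", frequency = 21,
                      value = 0.123456789012345, units = "coh")
  tf <- withr::local_tempfile(fileext = ".tsv")
  jf <- withr::local_tempfile(fileext = ".json")
  write_results(tab, tf, "tsv")
  expect_identical(strsplit(readLines(tf)[1], "\t")[[1]],
                   c("key", "frequency", "value", "units"))
  write_results(tab, jf, "json")
  back <- read_results(jf, "json")
  expect_identical(back$value, tab$value)

  empty <- result_table()
  write_results(empty, tf, "tsv")
  expect_identical(length(readLines(tf)), 1L)

  expect_error(write_results(tab, tf, "xml"), "usage error")
  expect_error(result_table(key = "a", frequency = -5, value = 1, units = "x"),
               "negative frequency")
})
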