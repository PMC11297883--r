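test_that("recording constructor enforces its invariants", {
  d <- matrix(rnorm(20), 2, 10)
  expect_error(recording(d, fs = 100, channel_names = c("a", "a")), "unique")
  expect_error(recording(d, fs = 0, channel_names = c("a", "b")), "positive")
  expect_error(recording(d, fs = 100, channel_names = c("a", "b", "c")),
               "row count")
  d[1, 1] <- NA
  expect_error(recording(d, fs = 100, channel_names = c("a", "b")),
               "missing")
})

test_that("segmentation arithmetic matches the reference protocols", {
  # 3 min at 500 Hz, 21.25 s epochs -> 8 epochs of 10,625 samples
  rec <- recording(matrix(0, 2, 180 * 500), fs = 500,
                   channel_names = c("a", "b"), subject_id = "s1",
                   label = "ADHD")
  eps <- segment_recording(rec, 21.25)
  expect_length(eps, 8)
  expect_true(all(vapply(eps, function(e) ncol(e$data), 0L) == 10625))
  expect_equal(vapply(eps, `[[`, 0L, "index"), 0:7)
  expect_true(all(vapply(eps, `[[`, "", "label") == "ADHD"))

  # 4 s at 128 Hz -> one epoch of 512 samples
  rec2 <- recording(matrix(0, 1, 4 * 128), fs = 128, channel_names = "a")
  eps2 <- segment_recording(rec2, 4)
  expect_length(eps2, 1)
  expect_equal(ncol(eps2[[1]]$data), 512)

  # recording shorter than one epoch -> empty, not an error
  rec3 <- recording(matrix(0, 1, 10 * 100), fs = 100, channel_names = "a")
  expect_identical(segment_recording(rec3, 21.25), list())
})

test_that("epochs concatenate back to the head of the recording", {
  rec <- make_recording(C = 3, L = 1037, fs = 100)
  eps <- segment_recording(rec, 3)   # L = 300, 3 epochs, remainder dropped
  expect_length(eps, 3)
  glued <- do.call(cbind, lapply(eps, `[[`, "data"))
  expect_identical(glued, rec$data[, 1:900])
  expect_lte(sum(vapply(eps, function(e) ncol(e$data), 0L)), ncol(rec$data))
})

test_that("CSV recordings round-trip and honour montage order", {
  rec <- make_recording(C = 4, L = 64, fs = 32,
                        labels = c("Fp1", "Fp2", "F3", "F4"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording_csv(rec, path)
  back <- read_recording(path, "csv", montage = c("F3", "Fp1"), fs = 32)
  expect_equal(back$channel_names, c("F3", "Fp1"))
  expect_equal(back$data["F3", ], unname(rec$data["F3", ]), tolerance = 1e-12)
  expect_equal(back$fs, 32)
  expect_error(read_recording(path, "csv", montage = c("Cz"), fs = 32), "Cz")
  expect_error(read_recording(path, "csv", montage = "Fp1"), "fs")
})

test_that("EDF recordings round-trip within quantisation error", {
  labels <- c("Fp1", "Fp2", "F3", "F4", "P3", "P4", "O1", "O2", "F7",
              "F8", "T3", "T4", "Cz", "Pz", "Fz", "C3", "C4", "T5", "T6")
  rec <- make_recording(C = 19, L = 256, fs = 128, labels = labels)
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  # 19-channel file read through a 12-label montage -> 12 rows, in order
  back <- read_recording(path, "edf", montage = DEFAULT_MONTAGE)
  expect_equal(back$channel_names, DEFAULT_MONTAGE)
  expect_equal(nrow(back$data), 12)
  expect_equal(back$fs, 128)
  tol <- max(apply(rec$data, 1, function(r) diff(range(r)))) / 65535 * 2
  expect_lt(max(abs(back$data - rec$data[DEFAULT_MONTAGE, ])), tol)
  expect_error(read_recording(path, "edf", montage = c("Fp1", "XX9")), "XX9")
})

test_that("EDF channels with inconsistent sampling rates are rejected", {
  rec <- make_recording(C = 2, L = 100, fs = 50, labels = c("a", "b"))
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  # rewrite channel b's samples-per-record header field (offset: 256-byte
  # header + 2 x (16+80+8+8+8+8+8+80) signal fields + 8 for channel a)
  con <- file(path, "r+b")
  seek(con, 256 + 2 * 216 + 8, rw = "write")
  writeBin(charToRaw(formatC("50", width = -8)), con)
  close(con)
  expect_error(read_recording(path, "edf", montage = c("a", "b")),
               "inconsistent")
})
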