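# Recording container and on-disk formats.

test_that("default montage matches the 32-channel 10/10 layout in order", {
  m <- default_montage()
  expect_length(m$channel_names, 32)
  expect_identical(m$channel_names[1:5], c("Fp1", "Fp2", "Fz", "F3", "F4"))
  expect_identical(m$channel_names[30:32], c("Oz", "O1", "O2"))
  expect_false(anyDuplicated(m$channel_names) > 0)
  expect_error(montage(c("A", "A")), "unique")
})

test_that("recording validates shape, rate and event bounds", {
  m <- montage(c("A", "B"))
  x <- matrix(rnorm(2 * 500), 2)
  expect_s3_class(recording("p", x, m, 500), "eeg_recording")
  expect_error(recording("p", matrix(0, 3, 10), m, 500), "channels")
  expect_error(recording("p", x, m, 60), "sampling_rate")
  ev <- stimulus_events(0.5, 1.0, "s1", "original", 1L)
  expect_error(recording("p", x, m, 500, ev), "past end")
  # events sorted by onset regardless of construction order
  x2 <- matrix(rnorm(2 * 2000), 2)
  ev2 <- stimulus_events(c(2, 0, 1), rep(0.5, 3), c("a", "b", "c"),
                         rep("original", 3), 1:3)
  expect_equal(ev2$stimulus_id, c("b", "c", "a"))
  expect_error(stimulus_events(0, 1, "s", "poetry", 1L), "text_type")
})

test_that("channel access resolves through montage labels", {
  rec <- recording("p", rbind(A = 1:10, B = 11:20) * 1.0,
                   montage(c("A", "B")), 500)
  expect_equal(channel_data(rec, "B")[1, ], 11:20, ignore_attr = TRUE)
  expect_error(channel_data(rec, "Z"), "unknown channel")
})

test_that("native fixture round-trips samples, events and montage", {
  spec <- small_spec()
  d <- generate_design(spec)
  rec <- synthesize_recording(d$metadata[1, ], d$schedules[[1]], spec)
  prefix <- file.path(withr::local_tempdir(), "rec")
  write_recording(rec, prefix)
  back <- read_recording(prefix)
  expect_lt(max(abs(rec$samples - back$samples)), 1e-4)  # float32 storage
  expect_identical(rec$events, back$events)
  expect_identical(rec$montage$channel_names, back$montage$channel_names)
  expect_error(read_recording(file.path(tempdir(), "nope")), "missing file")
})

test_that("BrainVision triplet round-trips and errors name missing files", {
  spec <- small_spec()
  d <- generate_design(spec)
  rec <- synthesize_recording(d$metadata[1, ], d$schedules[[1]], spec)
  td <- withr::local_tempdir()
  write_brainvision(rec, file.path(td, "bv"))
  back <- read_brainvision(file.path(td, "bv.vhdr"))
  expect_lt(max(abs(rec$samples - back$samples)), 1e-4)
  expect_equal(nrow(back$events), nrow(rec$events))
  expect_equal(back$events$text_type, rec$events$text_type)
  expect_false(is.unsorted(back$events$onset_s))
  file.remove(file.path(td, "bv.eeg"))
  expect_error(read_brainvision(file.path(td, "bv.vhdr")), "bv\\.eeg")
})

test_that("EDF round-trips within 16-bit quantization and carries events", {
  spec <- small_spec(seed = 9)
  d <- generate_design(spec)
  rec <- synthesize_recording(d$metadata[1, ], d$schedules[[1]], spec)
  path <- file.path(withr::local_tempdir(), "rec.edf")
  step <- write_edf(rec, path)
  back <- read_edf(path)
  # quantization bound derived from the symmetric physical range
  expect_lte(max(abs(rec$samples -
                       back$samples[, seq_len(ncol(rec$samples))])),
             step / 2 + 1e-12)
  expect_equal(nrow(back$events), nrow(rec$events))
  expect_equal(back$events$onset_s, rec$events$onset_s, tolerance = 1e-4)
  expect_equal(back$events$stimulus_id, rec$events$stimulus_id)
})

test_that("EDF handles empty annotations and rejects truncated/non-EDF", {
  x <- matrix(sin(seq_len(1000) / 10), 2, byrow = TRUE) * 50
  rec <- recording("p0", x, montage(c("C3", "C4")), 500)
  td <- withr::local_tempdir()
  path <- file.path(td, "empty.edf")
  write_edf(rec, path)
  back <- read_edf(path)
  expect_equal(nrow(back$events), 0)
  # truncated: chop the data records
  raw <- readBin(path, "raw", file.size(path))
  writeBin(raw[1:(length(raw) - 500)], file.path(td, "trunc.edf"))
  expect_error(read_edf(file.path(td, "trunc.edf")), "truncated")
  writeLines("not an edf at all", file.path(td, "bad.edf"))
  expect_error(read_edf(file.path(td, "bad.edf")), "magic")
})

test_that("feature tables round-trip and keep one row per channel", {
  spec <- small_spec()
  d <- generate_design(spec)
  rec <- synthesize_recording(d$metadata[1, ], d$schedules[[1]], spec)
  f <- spectral_features(rec)
  expect_equal(nrow(f), nrow(rec$events) * 32)
  path <- file.path(withr::local_tempdir(), "features.tsv")
  write_features_table(f, path)
  back <- read_features_table(path)
  expect_equal(dim(back), dim(f))
  expect_equal(back$channel, f$channel)
  num <- vapply(f, is.numeric, TRUE)
  expect_equal(as.matrix(back[, num]), as.matrix(f[, num]),
               tolerance = 1e-9, ignore_attr = TRUE)
  # header-only file for an empty table
  write_features_table(f[0, ], path)
  expect_equal(nrow(read_features_table(path)), 0)
})
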