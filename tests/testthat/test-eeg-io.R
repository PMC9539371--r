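test_that("EDF round trip preserves samples within 16-bit quantization", {
  rec <- tiny_cohort$recordings[[1]]
  path <- tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_edf(path)
  expect_equal(back$rate_hz, rec$rate_hz)
  expect_identical(back$channel_names, rec$channel_names)
  expect_equal(back$patient_id, rec$patient_id)
  n <- ncol(rec$samples)
  pr <- 2 * max(1, ceiling(max(abs(rec$samples))))   # physical range
  q <- pr / 65535
  expect_lt(max(abs(back$samples[, 1:n] - rec$samples)), q / 2 + 1e-12)
})

test_that("EDF header arithmetic gives the expected sample grid", {
  t <- (0:(256 * 60 - 1)) / 256
  x <- matrix(10 * sin(2 * pi * 7 * t), 16, length(t), byrow = TRUE)
  rec <- swd_recording(x, 256, channels_1020(), patient_id = "HDR")
  path <- tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_edf(path)
  expect_equal(dim(back$samples), c(16L, 15360L))
})

test_that("read_recording validates annotations against the recording", {
  rec <- tiny_cohort$recordings[[1]]
  path <- tempfile(fileext = ".edf")
  write_edf(rec, path)
  ev <- tiny_cohort$events[tiny_cohort$events$patient_id == rec$patient_id, ]
  csv <- tempfile(fileext = ".csv")
  write.csv(ev, csv, row.names = FALSE)
  got <- read_recording(path, csv)
  expect_equal(nrow(got$events), nrow(ev))
  # offset beyond the recording end must be rejected
  ev$offset_s[1] <- recording_duration(rec) + 5
  write.csv(ev, csv, row.names = FALSE)
  expect_error(read_recording(path, csv), "beyond recording end")
  expect_error(read_recording(tempfile(fileext = ".edf"), csv), "not found")
})

test_that("write_dataset/read_recording round trip a cohort", {
  dir <- tempfile("cohort_")
  paths <- write_dataset(tiny_cohort$recordings[1:2],
                         tiny_cohort$events, dir)
  got <- read_recording(paths$edf[1], paths$annotations)
  expect_equal(got$recording$patient_id,
               tiny_cohort$recordings[[1]]$patient_id)
  expect_true(all(got$events$patient_id == got$recording$patient_id))
})

test_that("preprocess resamples, filters and re-references", {
  t <- (0:(500 * 10 - 1)) / 500
  x <- matrix(rnorm(16 * length(t)), 16)
  x <- x + matrix(30 * sin(2 * pi * 5 * t), 16, length(t), byrow = TRUE)
  rec <- swd_recording(x, 500, channels_1020(), patient_id = "RS")
  out <- preprocess(rec, target_rate_hz = 256)
  expect_equal(out$rate_hz, 256)
  expect_lt(abs(recording_duration(out) - 10), 1 / 256)
  # common average: per-sample channel mean is 0 within 1e-9
  expect_lt(max(abs(colMeans(out$samples))), 1e-9)
  expect_equal(out$reference, "common_average")
  expect_error(preprocess(rec, channel_subset = c("Fp1", "XX")), "XX")
  expect_error(preprocess(rec, target_rate_hz = 1000), "exceeds native")
})

test_that("modern channel labels map onto the classic 10-20 subset", {
  expect_equal(normalize_channel_names(c("EEG T7", "P8", "fp1", "F3-Ref")),
               c("T3", "T6", "Fp1", "F3"))
  t <- (0:999) / 250
  x <- matrix(rnorm(16 * 1000), 16)
  rec <- swd_recording(x, 250, sub("^T3$", "T7", channels_1020()),
                       patient_id = "AL")
  out <- preprocess(rec, 250, band_pass = FALSE)
  expect_identical(out$channel_names, channels_1020())
})

test_that("window extraction is half-open with exact sample counts", {
  rec <- sine_recording(dur_s = 20, fs = 256)
  ev <- swd_events("S01", onset_s = 10, offset_s = 12)
  wp <- extract_windows(rec, ev[1, ], window_config(1000, 500))
  expect_equal(ncol(wp$preictal), 256L)
  expect_equal(ncol(wp$ictal), 128L)
  # onset sample belongs to the ictal window
  i_on <- round(10 * 256)
  expect_identical(wp$ictal[, 1], rec$samples[, i_on + 1])
  expect_identical(wp$preictal[, 256], rec$samples[, i_on])
})

test_that("events too close to the recording edge are skipped with a signal", {
  rec <- sine_recording(dur_s = 20)
  ev <- swd_events("S01", onset_s = 0.5, offset_s = 2)
  expect_warning(res <- extract_windows(rec, ev[1, ], window_config(1000, 500)),
                 class = "swd_window_skip")
  expect_null(suppressWarnings(
    extract_windows(rec, ev[1, ], window_config(1000, 500))))
  ew <- extract_all_windows(list(rec), ev, window_config(1000, 500))
  expect_equal(length(ew$pairs), 0L)
  expect_equal(nrow(ew$skipped), 1L)
})

test_that("window extraction is translation-equivariant", {
  set.seed(99)
  x <- matrix(rnorm(2 * 256 * 20), 2)
  rec <- swd_recording(x, 256, c("A", "B"), patient_id = "T")
  k <- 64                                   # shift by k samples
  rec2 <- swd_recording(x[, -(1:k)], 256, c("A", "B"), patient_id = "T")
  ev1 <- swd_events("T", onset_s = 10, offset_s = 11)
  ev2 <- swd_events("T", onset_s = 10 - k / 256, offset_s = 11 - k / 256)
  w1 <- extract_windows(rec, ev1[1, ], window_config(1000, 500))
  w2 <- extract_windows(rec2, ev2[1, ], window_config(1000, 500))
  expect_identical(w1$preictal, w2$preictal)
  expect_identical(w1$ictal, w2$ictal)
})

test_that("window config enforces the searched ranges", {
  expect_error(window_config(pre_ms = 100000), "allow_extrapolation")
  expect_error(window_config(ict_ms = 50), "100")
  wc <- window_config(pre_ms = 100000, allow_extrapolation = TRUE)
  expect_equal(wc$pre_ms, 100000)
})
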