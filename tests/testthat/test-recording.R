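test_that("recording constructor enforces its invariants", {
  expect_s3_class(lfp_recording(rnorm(100), fs = 1000), "lfp_recording")
  expect_error(lfp_recording(rnorm(100), fs = 0), "positive")
  expect_error(lfp_recording(c(1, NA, 3), fs = 10), "NA")
  expect_error(lfp_recording(matrix(0, 2, 10), fs = 10,
                             channel_depths = c(0)), "per channel")
  expect_error(lfp_recording(rnorm(10), fs = 10,
                             valid = c(TRUE, FALSE)), "valid")
})

test_that("binary container round-trips samples and metadata", {
  rec <- generate_lfp(synth_spec(noise = list(sd_uv = 5)), 10, 1000,
                      seed = 1)
  rec$valid[2001:2500] <- FALSE
  path <- withr::local_tempfile(fileext = ".dat")

  write_recording(rec, path, encoding = "float64")
  back <- read_recording(path)
  expect_identical(back$samples, rec$samples)   # bit-exact for float64
  expect_identical(back$valid, rec$valid)
  expect_equal(back$fs, rec$fs)

  # int16 is exact to within one quantization step of the declared gain
  write_recording(rec, path, encoding = "int16", scale_uv = 0.195)
  back16 <- read_recording(path)
  expect_lt(max(abs(back16$samples - rec$samples)), 0.195 / 2 + 1e-9)
})

test_that("declared int16 scaling and probe geometry are applied on read", {
  # 2-channel, 1 kHz, 10 s int16 payload with gain 0.195 uV/bit
  raw <- matrix(as.numeric(sample(-100:100, 20000, replace = TRUE)), 2)
  rec <- lfp_recording(raw * 0.195, fs = 1000)
  path <- withr::local_tempfile(fileext = ".dat")
  write_recording(rec, path, encoding = "int16", scale_uv = 0.195)
  back <- read_recording(path)
  expect_equal(n_samples(back), 10000)
  expect_equal(back$samples, raw * 0.195)

  # 16-channel probe with 0..750 um depths reads back with 50 um spacing
  probe <- lfp_recording(matrix(rnorm(16 * 100), 16), fs = 1000,
                         channel_depths = seq(0, 750, by = 50))
  write_recording(probe, path)
  expect_equal(unique(diff(read_recording(path)$channel_depths)), 50)
})

test_that("corrupt containers raise integrity and format errors", {
  rec <- lfp_recording(rnorm(1000), fs = 1000)
  path <- withr::local_tempfile(fileext = ".dat")
  write_recording(rec, path)
  # truncate the payload below the declared length
  full <- readBin(path, "raw", n = file.size(path))
  writeBin(full[1:(length(full) - 256)], path)
  expect_error(read_recording(path), "integrity")
  # remove a required sidecar field
  meta <- jsonlite::read_json(paste0(path, ".json"))
  meta$fs <- NULL
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  expect_error(read_recording(path), "format")
  file.remove(paste0(path, ".json"))
  expect_error(read_recording(path), "sidecar")
})

test_that("alternating schedules cut a recording into the expected epochs", {
  rec <- lfp_recording(rnorm(60000), fs = 1000)

  s22 <- alternating_schedule(60, on_s = 2, off_s = 2, stim_hz = 40)
  ep <- extract_epochs(rec, s22)
  expect_equal(sum(ep$label == "ON"), 15)
  expect_equal(sum(ep$label == "OFF"), 15)
  # equal durations give equal sample counts per epoch
  expect_equal(length(unique(ep$i1 - ep$i0)), 1)

  s55 <- alternating_schedule(60, on_s = 5, off_s = 5, stim_hz = 10)
  ep5 <- extract_epochs(rec, s55)
  expect_equal(sum(ep5$label == "ON"), 6)
  expect_equal(sum(ep5$label == "OFF"), 6)

  empty <- stim_schedule(numeric(0), numeric(0), character(0))
  expect_equal(nrow(extract_epochs(rec, empty)), 0)

  # total labeled duration is conserved
  expect_equal(sum(ep$end_s - ep$start_s), sum(s22$end_s - s22$start_s))

  long <- stim_schedule(0, 61, "OFF")
  expect_error(extract_epochs(rec, long), "bounds")
})

test_that("schedule validation rejects malformed epoch lists", {
  expect_error(stim_schedule(c(0, 1), c(2, 3), c("OFF", "ON"),
                             stim_hz = c(NA, 40)), "overlap")
  expect_error(stim_schedule(0, 2, "ON", stim_hz = NA), "stim_hz")
  expect_error(stim_schedule(0, 2, "ON", stim_hz = 40, duty_cycle = 1.5),
               "duty_cycle")
  s <- alternating_schedule(20, stim_hz = 40)
  expect_true(all(s$duty_cycle == 0.5))
})

test_that("schedule and track CSV round-trip preserves content", {
  sched <- alternating_schedule(20, stim_hz = 40)
  f <- withr::local_tempfile(fileext = ".csv")
  write_schedule(sched, f)
  back <- read_schedule(f)
  expect_equal(back$start_s, sched$start_s)
  expect_equal(back$state, sched$state)

  tr <- generate_track(circle_arena(), "uniform", 60, 10, seed = 4)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_track(tr, f2)
  back2 <- read_track(f2, arena = circle_arena())
  expect_equal(back2$body_x_cm, tr$body_x_cm, tolerance = 1e-8)
  expect_equal(back2$nose_y_cm, tr$nose_y_cm, tolerance = 1e-8)
})
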