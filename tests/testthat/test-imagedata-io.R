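# Image-stack and tabular IO: TIFF round trips, metadata, record tables,
# config files.

test_that("TimeLapseStack validity and time axis", {
  st <- TimeLapseStack(array(1, c(2, 8, 8)), 30, 0.065)
  expect_equal(nFrames(st), 2)
  expect_equal(frameTimesMin(st), c(0, 0.5))
  expect_error(TimeLapseStack(array(1, c(1, 8, 8)), 30, 0.065),
               "at least 2 frames")
  expect_error(TimeLapseStack(array(1, c(2, 8, 8)), -30, 0.065), "positive")
  bad <- array(1, c(2, 8, 8)); bad[1, 1, 1] <- NA
  expect_error(TimeLapseStack(bad, 30, 0.065), "finite")
})

test_that("a 481-frame, 30 s stack spans 4 hours", {
  st <- TimeLapseStack(array(0, c(481, 8, 8)), 30, 0.065)
  expect_equal(max(frameTimesMin(st)), 240)   # 4 h in minutes
})

test_that("TIFF write/read round-trips pixel values exactly", {
  set.seed(11)
  arr <- array(rnorm(5 * 12 * 17, 100, 30), c(5, 12, 17))
  st <- TimeLapseStack(arr, 30, 0.065, originName = "rt")
  path <- withr::local_tempfile(fileext = ".tif")
  writeStack(st, path)
  back <- readStack(path, 30, 0.065)
  expect_identical(dim(back), dim(st))
  expect_equal(frames(back), frames(st), tolerance = 0)

  # integer depths survive for integer-valued data
  arr2 <- array(sample(0:65535, 2 * 6 * 6, replace = TRUE), c(2, 6, 6))
  st2 <- TimeLapseStack(arr2, 60, 0.1)
  writeStack(st2, path, bitDepth = "uint16")
  expect_equal(frames(readStack(path, 60, 0.1)), frames(st2) * 1.0,
               tolerance = 0)
})

test_that("readStack rejects unreadable, single-frame and color input", {
  expect_error(readStack("/no/such/file.tif", 30, 0.065), "cannot read")
  path <- withr::local_tempfile(fileext = ".tif")
  sporeflow:::.write_tiff_pages(list(matrix(1, 4, 4)), path)
  expect_error(readStack(path, 30, 0.065), "single-frame")

  # hand-craft a minimal RGB page: SamplesPerPixel = 3
  con <- file(path, "wb")
  u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeBin(charToRaw("II"), con); u16(42); u32(8 + 12)  # data then IFD
  writeBin(as.raw(rep(1, 12)), con)                     # 2x2 RGB, 8-bit
  entry <- function(tag, type, count, val) { u16(tag); u16(type); u32(count); u32(val) }
  u16(8)
  entry(256, 4, 1, 2); entry(257, 4, 1, 2); entry(258, 3, 1, 8)
  entry(259, 3, 1, 1); entry(262, 3, 1, 2); entry(273, 4, 1, 8)
  entry(277, 3, 1, 3); entry(279, 4, 1, 12)
  u32(0)
  close(con)
  expect_error(readStack(path, 30, 0.065), "grayscale")
})

test_that("record tables round-trip losslessly, including empty tables", {
  df <- records_from_counts(2, 1, 0)
  df$t_start_min <- c(10.123456789012345, 2 / 3, NA)
  df$generation_time_min <- c(62.00000000001, NA, NA)
  path <- withr::local_tempfile(fileext = ".csv")
  writeRecords(df, path)
  back <- readRecords(path)
  expect_equal(back$t_start_min, df$t_start_min, tolerance = 0)
  expect_equal(back$generation_time_min, df$generation_time_min,
               tolerance = 0)
  expect_identical(back$fate, df$fate)

  writeRecords(emptyRecords(), path)
  expect_equal(length(readLines(path)), 1)        # header only
  expect_equal(nrow(readRecords(path)), 0)
  expect_error(writeRecords(df, "/no/such/dir/x.csv"), "cannot write")
})

test_that("flat-key config files parse into a RunConfig", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# run configuration", "dark_threshold: 60",
               "burst_jump_fraction: 0.3", "fitMinR: 0.95"), path)
  cfg <- readRunConfig(path)
  expect_s4_class(cfg, "RunConfig")
  expect_equal(cfg@darkThreshold, 60)
  expect_equal(cfg@burstJumpFraction, 0.3)
  expect_equal(cfg@fitMinR, 0.95)
  writeLines("no_such_key: 1", path)
  expect_error(readRunConfig(path), "unknown config key")
})

test_that("RunConfig validity guards hold", {
  expect_error(runConfig(brightThreshold = 50, darkThreshold = 60),
               "darkThreshold")
  expect_error(runConfig(burstJumpFraction = 0), "burstJumpFraction")
  expect_error(runConfig(fitMinR = 1.2), "fitMinR")
})
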