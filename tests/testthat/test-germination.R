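# Germination-event detection: drop-range 90%/10% crossing times with
# linear interpolation, plateau estimation, and the module invariants.

sig_trace <- function(times, t0, dur, i_b = 180, i_d = 40, id = 1L) {
  tmid <- t0 + dur / 2
  s <- dur / (2 * log(9))
  data.frame(spore_id = id, time_min = times,
             intensity = i_d + (i_b - i_d) / (1 + exp((times - tmid) / s)))
}

cfg60 <- function(...) runConfig(darkThreshold = 60, ...)

test_that("scripted sigmoid events are recovered within one frame interval", {
  times <- seq(0, 30, by = 0.5)
  for (dur in c(2, 4, 7)) {
    ev <- detectGermination(sig_trace(times, t0 = 10, dur = dur), cfg60())
    expect_true(ev$detected)
    expect_lt(abs(ev$t_start_min - 10), 0.5)
    expect_lt(abs(ev$duration_min - dur), 0.5)
    expect_gt(ev$drop_range, 0)
    expect_lt(ev$t_start_min, ev$t_end_min)
  }
})

test_that("constant and never-dark traces are not events", {
  flat <- data.frame(spore_id = 1L, time_min = seq(0, 10, 0.5),
                     intensity = 180)
  ev <- detectGermination(flat, cfg60())
  expect_false(ev$detected)
  expect_false(ev$pre_germinated)
  # a dip that stays above the dark threshold is not germination
  shallow <- sig_trace(seq(0, 30, 0.5), 10, 4, i_b = 180, i_d = 100)
  expect_false(detectGermination(shallow, cfg60())$detected)
})

test_that("single-step drop: both crossings interpolate inside one interval", {
  tr <- data.frame(spore_id = 1L, time_min = seq(0, 7, 0.5),
                   intensity = c(rep(100, 5), rep(0, 10)))
  ev <- detectGermination(tr, runConfig(darkThreshold = 50))
  expect_true(ev$detected)
  # hand-computed on the single step segment (2.0 -> 2.5 min, 100 -> 0):
  # t90 = 2 + (100-90)/100 * 0.5 = 2.05; t10 = 2 + (100-10)/100 * 0.5 = 2.45
  expect_equal(ev$t_start_min, 2.05, tolerance = 1e-9)
  expect_equal(ev$t_end_min, 2.45, tolerance = 1e-9)
  expect_equal(ev$duration_min, 0.4, tolerance = 1e-9)
  expect_lte(ev$duration_min, 0.5)
})

test_that("spores already phase-dark at frame 0 are flagged, not timed", {
  tr <- data.frame(spore_id = 4L, time_min = seq(0, 10, 0.5), intensity = 40)
  ev <- detectGermination(tr, cfg60())
  expect_false(ev$detected)
  expect_true(ev$pre_germinated)
  expect_true(is.na(ev$t_start_min))
})

test_that("time-shift equivariance: k-frame shift moves both crossings by
           k intervals and leaves the duration unchanged", {
  times <- seq(0, 40, by = 0.5)
  tr <- sig_trace(times, 12, 4)
  base <- detectGermination(tr, cfg60())
  n <- length(times)
  for (k in c(3, 10)) {
    # shift the sampled trace itself by k frames (leading plateau padded)
    tr2 <- tr
    tr2$intensity <- c(rep(tr$intensity[1], k),
                       tr$intensity[seq_len(n - k)])
    ev <- detectGermination(tr2, cfg60())
    expect_equal(ev$t_start_min - base$t_start_min, k * 0.5,
                 tolerance = 1e-3)
    expect_equal(ev$t_end_min - base$t_end_min, k * 0.5, tolerance = 1e-3)
    expect_equal(ev$duration_min, base$duration_min, tolerance = 1e-3)
  }
})

test_that("intensity-affine invariance: v -> a*v + b with mapped thresholds
           leaves all event times unchanged", {
  times <- seq(0, 30, by = 0.5)
  tr <- sig_trace(times, 9, 5)
  base <- detectGermination(tr, cfg60())
  for (ab in list(c(2, 10), c(0.5, -7))) {
    a <- ab[1]; b <- ab[2]
    tr2 <- tr; tr2$intensity <- a * tr$intensity + b
    cfg2 <- runConfig(darkThreshold = a * 60 + b,
                      settleTolerance = a * 4)
    ev <- detectGermination(tr2, cfg2)
    expect_equal(ev$t_start_min, base$t_start_min, tolerance = 1e-8)
    expect_equal(ev$t_end_min, base$t_end_min, tolerance = 1e-8)
    expect_equal(ev$drop_range, a * base$drop_range, tolerance = 1e-8)
  }
})

test_that("a trace with two large drops uses the first and warns", {
  times <- seq(0, 40, by = 0.5)
  v <- sig_trace(times, 8, 3)$intensity
  v[times >= 25 & times < 30] <- 150   # transient recovery, second drop
  tr <- data.frame(spore_id = 1L, time_min = times, intensity = v)
  expect_warning(ev <- detectGermination(tr, cfg60()), "multiple drops")
  expect_lt(abs(ev$t_start_min - 8), 0.6)
})

test_that("summarizeGermination keeps only detected events", {
  times <- seq(0, 30, 0.5)
  evs <- rbind(detectGermination(sig_trace(times, 10, 4, id = 1L), cfg60()),
               detectGermination(sig_trace(times, 15, 3, id = 2L), cfg60()),
               detectGermination(data.frame(spore_id = 3L, time_min = times,
                                            intensity = 180), cfg60()))
  sg <- summarizeGermination(evs)
  expect_equal(length(sg$t_start_min), 2)
  expect_equal(length(sg$duration_min), 2)
  empty <- summarizeGermination(evs[evs$detected == FALSE, ])
  expect_equal(length(empty$t_start_min), 0)
})

test_that("extractTrace errors when the center disk is clipped", {
  fix <- single_spore_stack(fate = "dormant", nFrames = 5)
  mk <- data.frame(spore_id = 1L, centroid_y = 1, centroid_x = 60,
                   area_px = 10L, mean_intensity = 180, included = TRUE)
  expect_error(extractTrace(fix$stack, mk, 2), "boundary")
})
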