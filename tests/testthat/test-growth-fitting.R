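# Generation-time fitting from log2(area) windows and vegetative-cell mode.

test_that("an exact doubling law is recovered with r = 1", {
  tt <- seq(0, 120, by = 1)
  tr <- data.frame(time_min = tt, area_px2 = 50 * 2^(tt / 62))
  fit <- fitGenerationTime(tr, c(10, 110))
  expect_equal(fit$generation_time_min, 62, tolerance = 1e-9)
  expect_equal(fit$r_value, 1, tolerance = 1e-9)
  expect_false(fit$flagged)
})

test_that("constant areas are flagged with no generation time", {
  tr <- data.frame(time_min = 0:20, area_px2 = rep(100, 21))
  fit <- fitGenerationTime(tr, c(0, 20))
  expect_true(fit$flagged)
  expect_equal(fit$flag_reason, "nonpositive_slope")
  expect_true(is.na(fit$generation_time_min))
  expect_error(fitGenerationTime(tr, c(0, 2)), "fewer than 4")
})

test_that("5% multiplicative noise: generation time within 5%, |r| > 0.99", {
  # 60 samples over 177 min, the long clean exponential window of a
  # vegetative-mode movie
  tt <- seq(0, 177, by = 3)
  set.seed(31)
  for (rep in 1:20) {
    a <- 80 * 2^(tt / 62) * exp(rnorm(length(tt), 0, 0.05))
    fit <- fitGenerationTime(data.frame(time_min = tt, area_px2 = a),
                             c(0, 177))
    expect_lt(abs(fit$generation_time_min - 62) / 62, 0.05)
    expect_gt(abs(fit$r_value), 0.99)
  }
})

test_that("scale invariance: area units do not change slope, r or
           generation time", {
  tt <- seq(0, 100, by = 2)
  set.seed(7)
  a <- 60 * 2^(tt / 45) * exp(rnorm(length(tt), 0, 0.03))
  f1 <- fitGenerationTime(data.frame(time_min = tt, area_px2 = a), c(0, 100))
  f2 <- fitGenerationTime(data.frame(time_min = tt, area_px2 = 3.7 * a),
                          c(0, 100))
  expect_equal(f2$slope_doublings_per_min, f1$slope_doublings_per_min,
               tolerance = 1e-12)
  expect_equal(f2$r_value, f1$r_value, tolerance = 1e-12)
  expect_equal(f2$generation_time_min, f1$generation_time_min,
               tolerance = 1e-12)
  expect_equal(f2$intercept - f1$intercept, log2(3.7), tolerance = 1e-9)
})

test_that("time-unit consistency: fitting in hours converts exactly", {
  tt <- seq(0, 120, by = 2)
  set.seed(8)
  a <- 70 * 2^(tt / 55) * exp(rnorm(length(tt), 0, 0.02))
  f_min <- fitGenerationTime(data.frame(time_min = tt, area_px2 = a),
                             c(0, 120))
  f_hr <- fitGenerationTime(data.frame(time_min = tt / 60, area_px2 = a),
                            c(0, 2))
  expect_equal(f_hr$generation_time_min * 60, f_min$generation_time_min,
               tolerance = 1e-9)
})

test_that("default window runs from division to the end of the linear part", {
  cfg <- runConfig()
  tt <- seq(0, 120, by = 2)
  expo <- fake_area_trace(tt, 100 * 2^(tt / 30))
  win <- defaultFitWindow(expo, 40, cfg)
  expect_equal(win, c(40, 120))     # perfectly exponential to the end
  # growth plateaus at t = 80: the window must stop within one rolling
  # window (10 frames * 2 min) of the breakpoint
  a2 <- ifelse(tt <= 80, 100 * 2^(tt / 30), 100 * 2^(80 / 30))
  plat <- fake_area_trace(tt, a2)
  win2 <- defaultFitWindow(plat, 40, cfg)
  expect_false(is.null(win2))
  expect_lte(win2[2], 80 + 10 * 2)
  # censored before division: no window
  short <- fake_area_trace(tt[tt < 30], 100 * 2^(tt[tt < 30] / 30),
                           cens = 30, reason = "touch_colony")
  expect_null(defaultFitWindow(short, 40, cfg))
})

test_that("vegetative mode recovers scripted generation times within 5%", {
  for (gen in c(23.8, 68.9)) {
    sc <- sporeScripts(1:3, centroid_y = c(50, 50, 130),
                       centroid_x = c(50, 140, 95), fate = "vegetative",
                       generation_time_min = gen, spore_radius_px = 5)
    man <- groundTruthManifest(sc, frameIntervalS = 120, noiseSd = 1)
    st <- simulateMovie(man, 60, c(190, 190), seed = 17)
    fits <- vegetativeMode(st, data.frame(centroid_y = sc$centroid_y,
                                          centroid_x = sc$centroid_x),
                           runConfig())
    expect_equal(nrow(fits), 3)
    expect_false(any(fits$flagged))
    expect_lt(abs(mean(fits$generation_time_min) - gen) / gen, 0.05)
  }
})

test_that("a flat vegetative marker is flagged without a fit", {
  sc <- sporeScripts(1L, 60, 60, "dormant")
  man <- groundTruthManifest(sc, frameIntervalS = 120, noiseSd = 0)
  st <- simulateMovie(man, 20, c(120, 120), seed = 2)
  fits <- vegetativeMode(st, data.frame(centroid_y = 60, centroid_x = 60),
                         runConfig())
  expect_true(fits$flagged[1])
  expect_true(is.na(fits$generation_time_min[1]))
})
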