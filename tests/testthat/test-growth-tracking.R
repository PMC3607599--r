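# Colony area tracking with censoring, first-division detection, burst
# detection and the outgrowth-time arithmetic.

test_that("tracked areas follow the scripted law within rasterization error", {
  fix <- single_spore_stack(fate = "outgrow", t0 = 6, dur = 4, t_div = 30,
                            gen = 20, nFrames = 40, frameIntervalS = 120,
                            shape = c(160, 160), noiseSd = 0)
  mk <- detectSpores(fix$stack, runConfig())
  at <- trackAreas(fix$stack, mk, runConfig())[[1]]
  expect_s4_class(at, "AreaTrace")
  # compare after the end of germination (the fading gray phase in between
  # is not a contour measurement)
  sel <- at@timesMin > 12
  a_true <- scriptedArea(fix$scripts, at@timesMin[sel])
  perim <- 2 * pi * sqrt(a_true / pi)
  expect_true(all(abs(at@areasPx2[sel] - a_true) < 2 * perim + 10))
})

test_that("colonies scripted to meet are censored as touch_colony by the
           scripted contact time", {
  # two outgrowing spores, lobe axes along the joining line; contact when
  # the two footprint extents (1.95 * lobe radius each) span the distance
  gen <- 20; t_div <- 30
  lobe <- sporeflow:::.LOBE_SEP_FACTOR / 2 + 1
  coef <- sporeflow:::.LOBE_UNION_COEF
  t_meet <- 70
  a_meet <- scriptedArea(
    sporeScripts(1L, 0, 0, "outgrow", t_germ_start_min = 6,
                 germ_duration_min = 4, t_first_division_min = t_div,
                 generation_time_min = gen), t_meet)
  D <- 2 * lobe * sqrt(a_meet / coef)
  sc <- sporeScripts(1:2, centroid_y = c(100, 100),
                     centroid_x = c(100 - D / 2, 100 + D / 2),
                     fate = "outgrow", t_germ_start_min = 6,
                     germ_duration_min = 4, t_first_division_min = t_div,
                     generation_time_min = gen, lobe_axis_deg = 0)
  man <- groundTruthManifest(sc, frameIntervalS = 120, noiseSd = 0)
  st <- simulateMovie(man, 45, c(200, 200), seed = 4)
  ats <- trackAreas(st, detectSpores(st, runConfig()), runConfig())
  for (at in ats) {
    expect_equal(censorReason(at), "touch_colony")
    expect_lte(censoredAtMin(at), t_meet)
    expect_gt(censoredAtMin(at), t_div)
  }
})

test_that("a dormant spore keeps a small constant area to the end", {
  fix <- single_spore_stack(fate = "dormant", nFrames = 20)
  mk <- detectSpores(fix$stack, runConfig())
  at <- trackAreas(fix$stack, mk, runConfig())[[1]]
  expect_equal(censorReason(at), "end_of_movie")
  expect_true(is.na(censoredAtMin(at)))
  expect_equal(length(at@timesMin), 20)
  expect_equal(diff(range(at@areasPx2)), 0)
})

test_that("a colony reaching the border is censored as touch_boundary", {
  sc <- sporeScripts(1L, 30, 30, "outgrow", t_germ_start_min = 4,
                     germ_duration_min = 3, t_first_division_min = 20,
                     generation_time_min = 12, lobe_axis_deg = 45)
  man <- groundTruthManifest(sc, frameIntervalS = 120, noiseSd = 0)
  st <- simulateMovie(man, 40, c(60, 60), seed = 4)
  at <- trackAreas(st, detectSpores(st, runConfig()), runConfig())[[1]]
  expect_equal(censorReason(at), "touch_boundary")
  expect_false(is.na(censoredAtMin(at)))
})

test_that("censoring monotonicity: larger collision margins never censor
           later", {
  sc <- sporeScripts(1:2, centroid_y = c(80, 80), centroid_x = c(55, 105),
                     fate = "outgrow", t_germ_start_min = 6,
                     germ_duration_min = 4, t_first_division_min = 25,
                     generation_time_min = 15, lobe_axis_deg = 0)
  man <- groundTruthManifest(sc, frameIntervalS = 120, noiseSd = 0)
  st <- simulateMovie(man, 45, c(160, 160), seed = 4)
  mk <- detectSpores(st, runConfig())
  prev <- Inf
  for (m in c(0, 1, 2, 4)) {
    at <- trackAreas(st, mk, runConfig(collisionMarginPx = m))[[1]]
    cens <- censoredAtMin(at)
    if (is.na(cens)) cens <- Inf
    expect_lte(cens, prev)
    prev <- cens
  }
})

test_that("disjoint colony areas add up to the total foreground", {
  fix <- population_stack(6, 1, 0, seed = 12, noiseSd = 0, nFrames = 22)
  st <- fix$stack
  cfg <- resolveConfig(st, runConfig())
  ats <- trackAreas(st, detectSpores(st, cfg), cfg)
  tt <- frameTimesMin(st)
  for (f in c(1, 20, 22)) {
    per_spore <- vapply(ats, function(a) {
      i <- match(tt[f], a@timesMin)
      if (is.na(i)) NA_real_ else a@areasPx2[i]
    }, numeric(1))
    if (anyNA(per_spore)) next
    frame <- getFrame(st, f)
    total <- sum(abs(frame - median(frame)) > cfg@colonyDelta)
    expect_equal(sum(per_spore), total)
  }
})

test_that("first division is detected within two frames of the script", {
  fix <- single_spore_stack(fate = "outgrow", t0 = 10, dur = 4, t_div = 254,
                            gen = 62, nFrames = 135, frameIntervalS = 120,
                            shape = c(100, 100), noiseSd = 0)
  mk <- detectSpores(fix$stack, runConfig())
  at <- trackAreas(fix$stack, mk, runConfig())[[1]]
  div <- detectFirstDivision(fix$stack, at, mk[1, ], runConfig())
  expect_false(is.null(div))
  expect_equal(div$source, "auto")
  expect_lte(abs(div$t_division_min - 254), 2 * 2)
})

test_that("germinate-only spores yield no division; manual overrides win", {
  fix <- single_spore_stack(fate = "germinate_only", t0 = 8, dur = 4,
                            nFrames = 30)
  mk <- detectSpores(fix$stack, runConfig())
  at <- trackAreas(fix$stack, mk, runConfig())[[1]]
  expect_null(detectFirstDivision(fix$stack, at, mk[1, ], runConfig()))
  man <- data.frame(spore_id = 1L, t_division_min = 100.0)
  div <- detectFirstDivision(fix$stack, at, mk[1, ], runConfig(),
                             manualDivisions = man)
  expect_equal(div$t_division_min, 100.0)
  expect_equal(div$source, "manual")
})

test_that("a scripted 40% jump is reported as one burst at the right frame", {
  fix <- single_spore_stack(fate = "outgrow", t0 = 6, dur = 4, t_div = 40,
                            gen = 20, burst_t = 24, burst_j = 0.4,
                            nFrames = 45, frameIntervalS = 120,
                            shape = c(160, 160), noiseSd = 0)
  mk <- detectSpores(fix$stack, runConfig())
  cfg <- resolveConfig(fix$stack, runConfig(burstJumpFraction = 0.2))
  at <- trackAreas(fix$stack, mk, cfg)[[1]]
  ev <- detectGermination(extractTrace(fix$stack, mk[1, ], 2), cfg)
  div <- detectFirstDivision(fix$stack, at, mk[1, ], cfg)
  bursts <- detectBurst(at, ev, div, cfg)
  expect_equal(nrow(bursts), 1)
  expect_lte(abs(bursts$t_burst_min - 24), 2)
  expect_gte(bursts$relative_jump, 0.2)
})

test_that("smooth growth yields no burst; jumps outside the outgrowth
           window are not reported", {
  tt <- seq(0, 60, by = 2)
  smooth <- fake_area_trace(tt, 100 * 2^(tt / 20))
  germ <- data.frame(spore_id = 1L, detected = TRUE, pre_germinated = FALSE,
                     i_pre = 180, i_post = 40, drop_range = 140,
                     t_start_min = 6, t_end_min = 10, duration_min = 4)
  div <- data.frame(spore_id = 1L, t_division_min = 40, source = "auto")
  cfg <- runConfig(burstJumpFraction = 0.2)
  expect_equal(nrow(detectBurst(smooth, germ, div, cfg)), 0)
  # 40% step at t = 6 min, before the end of germination: outside window
  a <- 100 * 2^(tt / 20); a[tt >= 6] <- a[tt >= 6] * 1.4
  early <- fake_area_trace(tt, a)
  expect_equal(nrow(detectBurst(early, germ, div, cfg)), 0)
  expect_error(detectBurst(smooth, germ[0, ], div, cfg), "detected")
  expect_equal(nrow(detectBurst(smooth, germ, NULL, cfg)), 0)
})

test_that("outgrowth time is division minus end of germination", {
  germ <- data.frame(spore_id = 1L, detected = TRUE, pre_germinated = FALSE,
                     i_pre = 180, i_post = 40, drop_range = 140,
                     t_start_min = 46, t_end_min = 50, duration_min = 4)
  div <- data.frame(spore_id = 1L, t_division_min = 304, source = "manual")
  expect_equal(outgrowthTime(germ, div), 254)
  expect_true(is.na(outgrowthTime(germ, NULL)))
  bad <- div; bad$t_division_min <- 40
  expect_error(outgrowthTime(germ, bad), "precedes")
})
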