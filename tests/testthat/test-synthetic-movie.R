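# The forward simulator: scripted laws, determinism, geometry guards,
# manifest IO.

test_that("dormant spore center intensity is constant (noise-free)", {
  fix <- single_spore_stack(fate = "dormant", nFrames = 10, noiseSd = 0)
  mk <- detectSpores(fix$stack, runConfig())
  tr <- extractTrace(fix$stack, mk[1, ], 2)
  expect_equal(length(tr$intensity), 10)
  expect_equal(diff(range(tr$intensity)), 0)
  expect_equal(tr$intensity[1], 180)
})

test_that("rendered center trace follows the scripted sigmoid; its
           90%/10% crossings sit at the scripted start and end", {
  fix <- single_spore_stack(fate = "germinate_only", t0 = 10, dur = 4,
                            frameIntervalS = 30, nFrames = 60, noiseSd = 0)
  mk <- detectSpores(fix$stack, runConfig())
  tr <- extractTrace(fix$stack, mk[1, ], 2)
  expected <- scriptedCenterIntensity(fix$scripts, tr$time_min)
  expect_equal(tr$intensity, expected, tolerance = 1e-12)

  # closed-form crossings of the logistic: by construction the 90% (10%)
  # level of the full i_bright->i_dark range is crossed at t0 (t0 + dur)
  rng <- 180 - 40
  l90 <- 40 + 0.9 * rng; l10 <- 40 + 0.1 * rng
  s <- 4 / (2 * log(9)); tmid <- 10 + 2
  t90 <- tmid + s * log((180 - l90) / (l90 - 40))
  t10 <- tmid + s * log((180 - l10) / (l10 - 40))
  expect_equal(t90, 10, tolerance = 1e-12)
  expect_equal(t10, 14, tolerance = 1e-12)

  # and the event detector recovers them within one frame interval
  ev <- detectGermination(tr, resolveConfig(fix$stack, runConfig()))
  expect_true(ev$detected)
  expect_lt(abs(ev$t_start_min - 10), 0.5)
  expect_lt(abs(ev$duration_min - 4), 0.5)
})

test_that("same manifest and seed give bit-identical stacks", {
  p <- compressed_params(0.8, 0.5)
  side <- grid_side(9)
  sc <- randomSporeScripts(9, c(side, side), p, seed = 5)
  man <- groundTruthManifest(sc, frameIntervalS = 120, noiseSd = 3)
  a <- simulateMovie(man, 12, c(side, side), seed = 42)
  b <- simulateMovie(man, 12, c(side, side), seed = 42)
  expect_identical(frames(a), frames(b))
  c2 <- simulateMovie(man, 12, c(side, side), seed = 43)
  expect_false(identical(frames(a), frames(c2)))
})

test_that("overlapping or out-of-frame spores are rejected", {
  sc <- sporeScripts(1:2, c(30, 35), c(30, 33), c("dormant", "dormant"))
  man <- groundTruthManifest(sc, minSeparationPx = 18)
  expect_error(simulateMovie(man, 5, c(80, 80)), "overlapping")
  sc2 <- sporeScripts(1L, 200, 30, "dormant")
  expect_error(simulateMovie(groundTruthManifest(sc2), 5, c(80, 80)),
               "outside")
})

test_that("rendered mask area follows the scripted area law within a
           perimeter-proportional rasterization bound", {
  fix <- single_spore_stack(fate = "outgrow", t0 = 6, dur = 4, t_div = 30,
                            gen = 20, nFrames = 40, frameIntervalS = 120,
                            shape = c(160, 160), noiseSd = 0)
  st <- fix$stack
  bg <- 100
  for (f in c(10, 20, 30, 40)) {   # 18..78 min: outgrowth + colony growth
    t <- frameTimesMin(st)[f]
    a_true <- scriptedArea(fix$scripts, t)
    mask <- abs(getFrame(st, f) - bg) > 20
    a_meas <- sum(mask)
    perim <- 2 * pi * sqrt(a_true / pi)
    expect_lt(abs(a_meas - a_true), 2 * perim + 10)
  }
})

test_that("script invariant guards reject inconsistent timing", {
  expect_error(sporeScripts(1L, 20, 20, "outgrow", t_germ_start_min = 10,
                            germ_duration_min = 4,
                            t_first_division_min = 12,
                            generation_time_min = 25),
               "exceed the end of germination")
  expect_error(sporeScripts(1L, 20, 20, "germinate_only",
                            t_germ_start_min = 10,
                            germ_duration_min = -1), "duration")
  expect_error(sporeScripts(1L, 20, 20, "dormant", i_bright = 40,
                            i_dark = 180), "i_dark < i_bright")
})

test_that("manifests round-trip through their text format", {
  p <- compressed_params(0.9, 0.6)
  side <- grid_side(8)
  sc <- randomSporeScripts(8, c(side, side), p, seed = 2)
  man <- groundTruthManifest(sc, frameIntervalS = 45, noiseSd = 1.5)
  path <- withr::local_tempfile(fileext = ".csv")
  writeManifest(man, path)
  back <- readManifest(path)
  expect_equal(back$frameIntervalS, 45)
  expect_equal(back$noiseSd, 1.5)
  expect_equal(back$scripts$centroid_y, man$scripts$centroid_y,
               tolerance = 0)
  expect_identical(back$scripts$fate, man$scripts$fate)
})

test_that("scripted population fractions are recovered end-to-end", {
  # 12 spores: 6 outgrow, 3 germinate-only, 3 dormant (noise-free)
  fix <- population_stack(12, frac_germinated = 9 / 12,
                          frac_outgrown = 6 / 12, seed = 8, noiseSd = 0,
                          nFrames = 55)
  res <- analyzeStack(fix$stack, runConfig())
  truth <- table(fix$manifest$scripts$fate)
  got <- table(res$records$fate)
  expect_equal(unname(got["outgrow"]), unname(truth["outgrow"]))
  expect_equal(unname(got["germinate_only"]), unname(truth["germinate_only"]))
  expect_equal(unname(got["dormant"]), unname(truth["dormant"]))
  cf <- classifyFates(res$records)
  expect_equal(cf$fraction_germinated, 100 * 9 / 12)
  expect_equal(cf$fraction_outgrown, 100 * 6 / 12)
})
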