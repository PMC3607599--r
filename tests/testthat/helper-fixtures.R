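# Shared builders for the test suite. Movies are simulated on a compressed
# timeline (short starts, 30-min outgrowth, ~25-min generation times) so
# that whole life histories fit in a ~100-min, 50-frame desk-scale movie;
# the fractions and event definitions under test do not depend on the
# absolute time scale.

compressed_params <- function(frac_germinated = 1, frac_outgrown = 1) {
  list(frac_germinated = frac_germinated, frac_outgrown = frac_outgrown,
       start_mean_min = 15, start_sd_min = 5,
       duration_mean_min = 4, duration_sd_min = 0.9,
       outgrowth_mean_min = 30, outgrowth_sd_min = 4,
       generation_mean_min = 25, generation_sd_min = 3,
       i_bright = 180, i_dark = 40, spore_radius_px = 6)
}

# image side holding n spores on the randomSporeScripts grid (spacing 36,
# margin 20)
grid_side <- function(n, spacing = 36, margin = 20) {
  k <- ceiling(sqrt(n))
  2 * margin + (k - 1) * spacing
}

population_stack <- function(n, frac_germinated, frac_outgrown, seed,
                             nFrames = 50, frameIntervalS = 120,
                             noiseSd = 2, spacing = 36) {
  side <- grid_side(n, spacing)
  scripts <- randomSporeScripts(
    n, c(side, side), compressed_params(frac_germinated, frac_outgrown),
    seed = seed, spacingPx = spacing)
  man <- groundTruthManifest(scripts, frameIntervalS = frameIntervalS,
                             noiseSd = noiseSd)
  list(stack = simulateMovie(man, nFrames, c(side, side), seed = seed + 1),
       manifest = man)
}

# one isolated spore with explicit timing, small noise-free movie
single_spore_stack <- function(fate = "outgrow", t0 = 10, dur = 4,
                               t_div = 44, gen = 25, burst_t = NA,
                               burst_j = NA, nFrames = 60,
                               frameIntervalS = 120, shape = c(120, 120),
                               noiseSd = 0, seed = 3) {
  s <- sporeScripts(1L, shape[1] / 2, shape[2] / 2, fate,
                    t_germ_start_min = if (fate == "dormant") NA else t0,
                    germ_duration_min = if (fate == "dormant") NA else dur,
                    t_first_division_min = if (fate == "outgrow") t_div else NA,
                    generation_time_min =
                      if (fate %in% c("outgrow", "vegetative")) gen else NA,
                    burst_time_min = burst_t, burst_jump = burst_j)
  man <- groundTruthManifest(s, frameIntervalS = frameIntervalS,
                             noiseSd = noiseSd)
  list(stack = simulateMovie(man, nFrames, shape, seed = seed),
       scripts = s, manifest = man)
}

# hand-built AreaTrace (footprints are placeholders of the right length)
fake_area_trace <- function(times, areas, id = 1L,
                            reason = "end_of_movie", cens = NA_real_) {
  new("AreaTrace", sporeId = id, timesMin = times,
      areasPx2 = as.numeric(areas), areasUm2 = as.numeric(areas) * 0.065^2,
      censoredAtMin = cens, censorReason = reason,
      footprints = replicate(length(times), 1L, simplify = FALSE),
      imageDim = c(100L, 100L))
}

# record table built from fate counts (population_stats fixtures)
records_from_counts <- function(n_outgrow, n_germ_only, n_dormant,
                                condition = "control") {
  n <- n_outgrow + n_germ_only + n_dormant
  fate <- c(rep("outgrow", n_outgrow), rep("germinate_only", n_germ_only),
            rep("dormant", n_dormant))
  data.frame(
    spore_id = seq_len(n), origin = "fixture", condition = condition,
    fate = fate, centroid_y = NA_real_, centroid_x = NA_real_,
    t_start_min = ifelse(fate == "dormant", NA_real_, 20),
    germ_duration_min = ifelse(fate == "dormant", NA_real_, 4),
    t_germ_end_min = ifelse(fate == "dormant", NA_real_, 24),
    t_division_min = ifelse(fate == "outgrow", 50, NA_real_),
    division_source = ifelse(fate == "outgrow", "auto", NA_character_),
    outgrowth_time_min = ifelse(fate == "outgrow", 26, NA_real_),
    generation_time_min = ifelse(fate == "outgrow", 25, NA_real_),
    fit_r = NA_real_, burst_times_min = NA_character_,
    censored_at_min = NA_real_, censor_reason = "end_of_movie",
    stringsAsFactors = FALSE)
}
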