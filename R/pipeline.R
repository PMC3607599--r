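# End-to-end orchestration: detect -> germination -> growth -> fits over one
# or many stacks, pooled per condition, with an optional two-condition
# comparison, deterministic outputs and a structured log.

.log_line <- function(log, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  log$lines <- c(log$lines, msg)
  log
}

#' Analyze one time-lapse stack
#'
#' Runs the three analysis steps on one stack: spore detection in frame 0
#' (with manual exclusions), germination-event detection on the
#' center-intensity traces, and area tracking with first-division, burst,
#' outgrowth-time and generation-time extraction. Fate per spore:
#' `excluded`, `pre_germinated` (phase-dark at t = 0), `dormant` (no
#' bright-to-dark transition), `germinate_only` (transition but no
#' division), `outgrow` (transition and division).
#'
#' @param stack a [TimeLapseStack-class].
#' @param config a [RunConfig-class] (auto-resolved).
#' @param condition condition label attached to every record.
#' @param exclusions integer vector of manually excluded spore ids.
#' @param manualDivisions optional data.frame `(spore_id, t_division_min)`.
#' @param manualWindows optional data.frame `(spore_id, start_min, end_min)`.
#' @return list: `records` (data.frame), `markers`, `traces` (intensity),
#'   `events`, `areaTraces`, `fits`, `config` (resolved), `log` (character).
#' @export
analyzeStack <- function(stack, config = runConfig(), condition = "control",
                         exclusions = integer(0), manualDivisions = NULL,
                         manualWindows = NULL) {
  cfg <- resolveConfig(stack, config)
  log <- list(lines = character(0))
  log <- .log_line(log, "stack '", originName(stack), "': ",
                   nFrames(stack), " frames, thresholds bright=",
                   round(cfg@brightThreshold, 3), " dark=",
                   round(cfg@darkThreshold, 3), " colonyDelta=",
                   round(cfg@colonyDelta, 3))
  # detection sees the un-resolved config: an automatic threshold carries
  # the no-bright-phase guard, a researcher-set threshold is used verbatim
  markers <- detectSpores(stack, config)
  log <- .log_line(log, "detected ", nrow(markers), " phase-bright spores")
  d0 <- dim(stack@frames)
  clipped <- markers$included &
    (markers$centroid_y < cfg@centerRadiusPx |
       markers$centroid_y > d0[2] - 1 - cfg@centerRadiusPx |
       markers$centroid_x < cfg@centerRadiusPx |
       markers$centroid_x > d0[3] - 1 - cfg@centerRadiusPx)
  if (any(clipped)) {
    markers$included[clipped] <- FALSE
    log <- .log_line(log, "excluded (center region clipped by boundary): ",
                     paste(markers$spore_id[clipped], collapse = ", "))
  }
  markers <- applyExclusions(markers, exclusions)
  if (length(exclusions))
    log <- .log_line(log, "manually excluded: ",
                     paste(exclusions, collapse = ", "))
  dur <- (nFrames(stack) - 1) * frameIntervalS(stack) / 60
  if (!nrow(markers))
    return(list(records = emptyRecords(), markers = markers,
                traces = list(), events = NULL, areaTraces = list(),
                fits = NULL, config = cfg, log = log$lines,
                movieDurationMin = dur))
  inc <- markers[markers$included, , drop = FALSE]
  traces <- lapply(seq_len(nrow(inc)), function(i)
    extractTrace(stack, inc[i, , drop = FALSE], cfg@centerRadiusPx))
  names(traces) <- as.character(inc$spore_id)
  events <- do.call(rbind, lapply(traces, detectGermination, config = cfg))
  areaTraces <- trackAreas(stack, markers, cfg)
  records <- list(); fits <- list()
  for (i in seq_len(nrow(markers))) {
    id <- markers$spore_id[i]
    key <- as.character(id)
    rec <- data.frame(
      spore_id = as.integer(id), origin = originName(stack),
      condition = condition, fate = NA_character_,
      centroid_y = markers$centroid_y[i],
      centroid_x = markers$centroid_x[i],
      t_start_min = NA_real_, germ_duration_min = NA_real_,
      t_germ_end_min = NA_real_, t_division_min = NA_real_,
      division_source = NA_character_, outgrowth_time_min = NA_real_,
      generation_time_min = NA_real_, fit_r = NA_real_,
      burst_times_min = NA_character_, censored_at_min = NA_real_,
      censor_reason = NA_character_, stringsAsFactors = FALSE)
    if (!markers$included[i]) {
      rec$fate <- "excluded"
      records[[key]] <- rec
      next
    }
    ev <- events[events$spore_id == id, , drop = FALSE]
    at <- areaTraces[[key]]
    rec$censored_at_min <- censoredAtMin(at)
    rec$censor_reason <- censorReason(at)
    if (isTRUE(ev$pre_germinated)) {
      rec$fate <- "pre_germinated"
    } else if (!isTRUE(ev$detected)) {
      rec$fate <- "dormant"
    } else {
      rec$t_start_min <- ev$t_start_min
      rec$germ_duration_min <- ev$duration_min
      rec$t_germ_end_min <- ev$t_end_min
      div <- detectFirstDivision(stack, at, markers[i, , drop = FALSE],
                                 cfg, manualDivisions)
      if (is.null(div)) {
        rec$fate <- "germinate_only"
      } else {
        rec$fate <- "outgrow"
        rec$t_division_min <- div$t_division_min
        rec$division_source <- div$source
        rec$outgrowth_time_min <- outgrowthTime(ev, div)
        bursts <- detectBurst(at, ev, div, cfg)
        if (nrow(bursts))
          rec$burst_times_min <- paste(sprintf("%.17g", bursts$t_burst_min),
                                       collapse = ";")
        win <- NULL
        if (!is.null(manualWindows) && id %in% manualWindows$spore_id) {
          mw <- manualWindows[match(id, manualWindows$spore_id), ]
          win <- c(mw$start_min, mw$end_min)
        } else {
          win <- defaultFitWindow(at, div, cfg)
        }
        if (!is.null(win) &&
            sum(at@timesMin >= win[1] & at@timesMin <= win[2]) >= 4) {
          fit <- fitGenerationTime(at, win, fitMinR = cfg@fitMinR)
          fits[[key]] <- fit
          if (!fit$flagged || identical(fit$flag_reason, "low_r")) {
            rec$generation_time_min <- fit$generation_time_min
            rec$fit_r <- fit$r_value
          }
          if (fit$flagged)
            log <- .log_line(log, "spore ", id, ": fit flagged (",
                             fit$flag_reason, ")")
        } else {
          log <- .log_line(log, "spore ", id,
                           ": no qualifying fit window; excluded from ",
                           "generation-time statistics")
        }
      }
    }
    if (!is.na(censoredAtMin(at)))
      log <- .log_line(log, "spore ", id, ": censored at ",
                       round(censoredAtMin(at), 2), " min (",
                       censorReason(at), ")")
    records[[key]] <- rec
  }
  records <- do.call(rbind, c(records, list(make.row.names = FALSE)))
  list(records = records, markers = markers, traces = traces,
       events = events, areaTraces = areaTraces,
       fits = if (length(fits)) do.call(rbind, c(fits,
         list(make.row.names = FALSE))) else NULL,
       config = cfg, log = log$lines, movieDurationMin = dur)
}

#' Run the full pipeline over a run manifest
#'
#' Analyzes every stack of the manifest, pools records per condition,
#' writes the master record CSV, per-condition summary CSVs, the
#' two-condition comparison and delta CSVs when exactly two conditions are
#' present, diagnostic plots (PDF) and a structured log. Deterministic
#' given inputs and the config seed; rerunning with identical inputs yields
#' byte-identical CSVs.
#'
#' @param runManifest data.frame with columns `path`, `condition`,
#'   `frame_interval_s`, `pixel_size_um`; `condition` labels must be
#'   nonempty. The first condition (in order of appearance) is treated as
#'   the reference in deltas.
#' @param config a [RunConfig-class].
#' @param outputDir directory for all outputs (created if needed).
#' @param plots write overlay/histogram PDFs (default TRUE).
#' @return list: `records`, `summaries`, `comparisons` (or NULL),
#'   `deltas` (or NULL), `outputDir`, invisibly.
#' @export
runPipeline <- function(runManifest, config = runConfig(),
                        outputDir = ".", plots = TRUE) {
  stopifnot(is.data.frame(runManifest),
            all(c("path", "condition", "frame_interval_s",
                  "pixel_size_um") %in% names(runManifest)))
  if (any(!nzchar(runManifest$condition)))
    stop("condition labels must be nonempty")
  if (!all(file.exists(runManifest$path)))
    stop("missing stack file(s): ",
         paste(runManifest$path[!file.exists(runManifest$path)],
               collapse = ", "))
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  set.seed(as.integer(config@randomSeed) %% .Machine$integer.max)
  log <- character(0)
  for (cond in unique(runManifest$condition)) {
    iv <- unique(runManifest$frame_interval_s[runManifest$condition == cond])
    if (length(iv) > 1)
      warning("mixed frame intervals within condition '", cond, "': ",
              paste(iv, collapse = ", "))
  }
  all_records <- list()
  all_traces <- list()
  all_areas <- list()
  durations <- list()
  for (i in seq_len(nrow(runManifest))) {
    row <- runManifest[i, ]
    stack <- readStack(row$path, row$frame_interval_s, row$pixel_size_um,
                       originName = basename(row$path))
    res <- analyzeStack(stack, config, condition = row$condition)
    log <- c(log, res$log)
    if (!nrow(res$records)) {
      log <- c(log, paste0("stack '", originName(stack),
                           "' yielded zero spores; skipped"))
      next
    }
    all_records[[i]] <- res$records
    all_traces[[i]] <- res$traces
    all_areas[[i]] <- res$areaTraces
    durations[[row$condition]] <- res$movieDurationMin
  }
  records <- if (length(all_records))
    do.call(rbind, c(all_records, list(make.row.names = FALSE))) else
    emptyRecords()
  writeRecords(records, file.path(outputDir, "spore_records.csv"))
  conds <- unique(runManifest$condition)
  summaries <- lapply(conds, function(cond) {
    summarizeCondition(records[records$condition == cond, , drop = FALSE],
                       condition = cond,
                       movieDurationMin =
                         if (!is.null(durations[[cond]]))
                           durations[[cond]] else NA_real_)
  })
  names(summaries) <- conds
  sum_df <- do.call(rbind, lapply(summaries, function(s) {
    data.frame(condition = s$condition, n_assessed = s$n_assessed,
               n_germinated = s$n_germinated, n_outgrown = s$n_outgrown,
               fraction_germinated = s$fraction_germinated,
               fraction_outgrown = s$fraction_outgrown,
               t(vapply(s$metrics, function(m)
                 c(mean = m$mean, sd = m$sd, n = m$n), numeric(3))),
               stringsAsFactors = FALSE)
  }))
  write.csv(sum_df, file.path(outputDir, "condition_summaries.csv"),
            row.names = FALSE)
  comparisons <- NULL; deltas <- NULL
  if (length(conds) == 2) {
    a <- records[records$condition == conds[1], , drop = FALSE]
    b <- records[records$condition == conds[2], , drop = FALSE]
    comp <- list()
    for (mn in names(.TIMING_METRICS)) {
      col <- .TIMING_METRICS[[mn]]
      va <- a[[col]][is.finite(a[[col]])]
      vb <- b[[col]][is.finite(b[[col]])]
      if (length(va) >= 2 && length(vb) >= 2 &&
          (var(va) > 0 || var(vb) > 0))
        comp[[mn]] <- compareConditions(va, vb, mn)
      else
        log <- c(log, paste0("metric '", mn,
                             "': too few values for a comparison"))
    }
    if (length(comp)) {
      comparisons <- do.call(rbind, c(comp, list(make.row.names = FALSE)))
      write.csv(comparisons,
                file.path(outputDir, "condition_comparisons.csv"),
                row.names = FALSE)
    }
    deltas <- conditionDeltas(summaries[[conds[1]]], summaries[[conds[2]]])
    write.csv(deltas, file.path(outputDir, "condition_deltas.csv"),
              row.names = FALSE)
  } else if (length(conds) > 2) {
    log <- c(log, "more than two conditions: pairwise comparison not run")
  }
  if (plots) {
    tryCatch({
      plotIntensityTraces(unlist(all_traces, recursive = FALSE),
                          file.path(outputDir, "intensity_traces.pdf"))
      plotAreaTraces(unlist(all_areas, recursive = FALSE),
                     file.path(outputDir, "area_traces.pdf"))
      plotMetricHistograms(records,
                           file.path(outputDir, "metric_histograms.pdf"))
    }, error = function(e)
      log <<- c(log, paste0("plotting failed: ", conditionMessage(e))))
  }
  writeLines(log, file.path(outputDir, "pipeline_log.txt"))
  invisible(list(records = records, summaries = summaries,
                 comparisons = comparisons, deltas = deltas,
                 outputDir = outputDir))
}

#' Simulate an experiment to disk
#'
#' Writes a simulated movie (multi-page TIFF) plus its ground-truth
#' manifest, ready to be analyzed with [runPipeline()]. Defaults emulate
#' one untreated field-of-view experiment: 90 spores followed at 1 frame
#' per 30 s for 4 h (481 frames).
#'
#' @param outputDir output directory.
#' @param n number of spores (default 90).
#' @param condition `"control"` or `"stress"` population parameters.
#' @param nFrames frames (default 481).
#' @param frameIntervalS seconds per frame (default 30).
#' @param shape `(ny, nx)`; default sized to hold `n` spores.
#' @param noiseSd pixel noise sd.
#' @param seed integer seed (governs placement, timing draws and noise).
#' @param name file stem.
#' @return data.frame with one run-manifest row (`path`, `condition`,
#'   `frame_interval_s`, `pixel_size_um`) plus `manifest_path`.
#' @export
simulateExperiment <- function(outputDir, n = 90,
                               condition = c("control", "stress"),
                               nFrames = 481, frameIntervalS = 30,
                               shape = NULL, noiseSd = 2, seed = 1,
                               name = NULL) {
  condition <- match.arg(condition)
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(shape)) {
    side <- 2 * 20 + 36 * ceiling(sqrt(max(n, 1)))
    shape <- c(side, side)
  }
  if (is.null(name)) name <- paste0("sim_", condition)
  params <- sporePopulationDefaults(condition)
  scripts <- if (n > 0)
    randomSporeScripts(n, shape, params, seed = seed) else
    sporeScripts(1L, 20, 20, "dormant")[0, ]
  manifest <- groundTruthManifest(scripts, frameIntervalS = frameIntervalS,
                                  noiseSd = noiseSd)
  stack <- simulateMovie(manifest, nFrames, shape, seed = seed + 1)
  tiff_path <- file.path(outputDir, paste0(name, ".tif"))
  writeStack(stack, tiff_path)
  man_path <- file.path(outputDir, paste0(name, "_truth.csv"))
  writeManifest(manifest, man_path)
  data.frame(path = tiff_path, condition = condition,
             frame_interval_s = frameIntervalS,
             pixel_size_um = manifest$pixelSizeUm,
             manifest_path = man_path, stringsAsFactors = FALSE)
}
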