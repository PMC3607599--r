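# Generation-time fitting: ordinary least squares of log2(area) on time
# inside a window. The slope is in doublings per minute, so the generation
# time is its reciprocal; r is the Pearson correlation of the fit.

.trace_table <- function(areaTrace) {
  if (is(areaTrace, "AreaTrace")) {
    data.frame(time_min = areaTrace@timesMin, area_px2 = areaTrace@areasPx2)
  } else {
    stopifnot(is.data.frame(areaTrace),
              all(c("time_min", "area_px2") %in% names(areaTrace)))
    areaTrace[, c("time_min", "area_px2")]
  }
}

#' Fit a generation time from a log2(area) window
#'
#' `generation_time_min = 1 / slope` where the slope of
#' `log2(area) ~ time` is in doublings per minute. Fits with non-positive
#' slope carry no generation time and are flagged; fits with `|r|` below
#' `fitMinR` are flagged `low_r`.
#'
#' @param areaTrace an [AreaTrace-class] or a data.frame with columns
#'   `time_min`, `area_px2` (all points uncensored, positive area).
#' @param window `(start_min, end_min)` fit window.
#' @param fitMinR minimal acceptable |r| (default 0.99).
#' @param sporeId id used in the output (default taken from the trace).
#' @return one-row data.frame: `spore_id, window_start_min, window_end_min,
#'   slope_doublings_per_min, intercept, r_value, generation_time_min,
#'   flagged, flag_reason`.
#' @export
fitGenerationTime <- function(areaTrace, window, fitMinR = 0.99,
                              sporeId = NULL) {
  stopifnot(length(window) == 2, window[1] < window[2])
  tab <- .trace_table(areaTrace)
  if (is.null(sporeId))
    sporeId <- if (is(areaTrace, "AreaTrace")) areaTrace@sporeId else NA_integer_
  sel <- tab$time_min >= window[1] & tab$time_min <= window[2]
  tt <- tab$time_min[sel]; aa <- tab$area_px2[sel]
  if (length(tt) < 4)
    stop("fit window holds fewer than 4 points (", length(tt), ")")
  if (any(aa <= 0)) stop("non-positive area inside the fit window")
  y <- log2(aa)
  slope <- cov(tt, y) / var(tt)
  intercept <- mean(y) - slope * mean(tt)
  r <- if (sd(y) == 0) 0 else cor(tt, y)
  flagged <- FALSE; reason <- NA_character_
  gen <- NA_real_
  if (slope <= 0) {
    flagged <- TRUE; reason <- "nonpositive_slope"
  } else {
    gen <- 1 / slope
    if (abs(r) < fitMinR) { flagged <- TRUE; reason <- "low_r" }
  }
  data.frame(spore_id = sporeId, window_start_min = window[1],
             window_end_min = window[2], slope_doublings_per_min = slope,
             intercept = intercept, r_value = r,
             generation_time_min = gen, flagged = flagged,
             flag_reason = reason, stringsAsFactors = FALSE)
}

#' Default fit window: first division to the end of the linear part
#'
#' Starting at the first division, rolling 10-frame windows of
#' `log2(area) ~ time` advance while their local slope stays at or above
#' half the initial (first-window) slope; the window ends at the last time
#' covered by the last qualifying rolling window. The slope criterion makes
#' the breakpoint search robust to pixel-quantization noise, which can pull
#' a short window's |r| far below 1 even on perfectly exponential growth;
#' `fitMinR` is instead applied to the final fit over the whole window (the
#' scale on which the 0.99 quality bar is meaningful). Returns `NULL`
#' (spore excluded from generation-time statistics) when no qualifying
#' window exists, e.g. when the trace is censored before (or shortly after)
#' division.
#'
#' @param areaTrace an [AreaTrace-class] or area data.frame.
#' @param divisionEvent one-row event from [detectFirstDivision()], or a
#'   number (the start time in minutes).
#' @param config a [RunConfig-class]; `fitMinR` is taken from it.
#' @param windowFrames rolling-window length in frames (default 10).
#' @return `c(start_min, end_min)` or `NULL`.
#' @export
defaultFitWindow <- function(areaTrace, divisionEvent,
                             config = runConfig(), windowFrames = 10) {
  t_div <- if (is.numeric(divisionEvent)) divisionEvent else
    divisionEvent$t_division_min
  if (is.null(t_div) || !is.finite(t_div)) return(NULL)
  tab <- .trace_table(areaTrace)
  k0 <- which(tab$time_min >= t_div)[1]
  if (is.na(k0)) return(NULL)
  n <- nrow(tab)
  if (n - k0 + 1 < windowFrames) return(NULL)
  end_idx <- NA_integer_
  slope0 <- NA_real_
  for (i in k0:(n - windowFrames + 1)) {
    sel <- i:(i + windowFrames - 1)
    y <- log2(tab$area_px2[sel]); x <- tab$time_min[sel]
    sl <- cov(x, y) / var(x)
    if (is.na(slope0)) slope0 <- sl
    if (sl >= slope0 / 2) end_idx <- i + windowFrames - 1 else break
  }
  if (is.na(end_idx)) return(NULL)
  c(t_div, tab$time_min[end_idx])
}

#' Generation times of manually marked vegetative cells
#'
#' Vegetative-cell mode: germination detection is skipped; each manually
#' marked cell is area-tracked and fitted over the linear part of
#' log2(area) from t = 0 (same rolling-window rule as
#' [defaultFitWindow()]).
#'
#' @param stack a [TimeLapseStack-class].
#' @param manualMarkers data.frame with columns `centroid_y`, `centroid_x`
#'   (0-based pixels) or a list of `c(y, x)` pairs.
#' @param config a [RunConfig-class].
#' @return data.frame of [fitGenerationTime()] rows, one per marker; cells
#'   without a qualifying window are flagged `no_window`.
#' @export
vegetativeMode <- function(stack, manualMarkers, config = runConfig()) {
  if (!is.data.frame(manualMarkers)) {
    m <- do.call(rbind, lapply(manualMarkers, function(p)
      data.frame(centroid_y = p[1], centroid_x = p[2])))
    manualMarkers <- m
  }
  markers <- data.frame(spore_id = seq_len(nrow(manualMarkers)),
                        centroid_y = manualMarkers$centroid_y,
                        centroid_x = manualMarkers$centroid_x,
                        area_px = NA_integer_, mean_intensity = NA_real_,
                        included = TRUE)
  traces <- trackAreas(stack, markers, config)
  fits <- lapply(traces, function(tr) {
    win <- defaultFitWindow(tr, 0, config)
    if (is.null(win) || length(tr@timesMin) < 4) {
      return(data.frame(spore_id = tr@sporeId, window_start_min = NA_real_,
                        window_end_min = NA_real_,
                        slope_doublings_per_min = NA_real_,
                        intercept = NA_real_, r_value = NA_real_,
                        generation_time_min = NA_real_, flagged = TRUE,
                        flag_reason = "no_window",
                        stringsAsFactors = FALSE))
    }
    fitGenerationTime(tr, win, fitMinR = config@fitMinR)
  })
  do.call(rbind, c(fits, list(make.row.names = FALSE)))
}
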