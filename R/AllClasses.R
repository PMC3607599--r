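#' @include sporeflow-package.R
NULL

# ---- TimeLapseStack ---------------------------------------------------------

#' TimeLapseStack: an ordered grayscale time-lapse image stack
#'
#' The raw input of the pipeline: a 3-D intensity array indexed
#' (time, y, x), the acquisition interval in seconds, the pixel size in
#' micrometers and a free-text field-of-view label. Pixel coordinates are
#' 0-based (row, col); times are reported in minutes from frame 0,
#' `t = (frame_index) * frameInterval / 60`.
#'
#' @slot frames numeric 3-D array `(time, y, x)`; finite grayscale values.
#' @slot frameIntervalS seconds per frame, > 0.
#' @slot pixelSizeUm micrometers per pixel, > 0.
#' @slot originName free-text identifier of the field of view.
#'
#' @examples
#' st <- TimeLapseStack(array(0, c(2, 8, 8)), frameIntervalS = 30,
#'                      pixelSizeUm = 0.065)
#' nFrames(st)
#' frameTimesMin(st)
#' @export
setClass("TimeLapseStack",
  representation(
    frames = "array",
    frameIntervalS = "numeric",
    pixelSizeUm = "numeric",
    originName = "character"
  )
)

setValidity("TimeLapseStack", function(object) {
  msg <- character(0)
  d <- dim(object@frames)
  if (length(d) != 3L)
    msg <- c(msg, "frames must be a 3-D array (time, y, x)")
  else if (d[1] < 2L)
    msg <- c(msg, "a time-lapse stack needs at least 2 frames")
  if (!all(is.finite(object@frames)))
    msg <- c(msg, "frame intensities must be finite")
  if (length(object@frameIntervalS) != 1L || !is.finite(object@frameIntervalS) ||
      object@frameIntervalS <= 0)
    msg <- c(msg, "frameIntervalS must be a single positive number")
  if (length(object@pixelSizeUm) != 1L || !is.finite(object@pixelSizeUm) ||
      object@pixelSizeUm <= 0)
    msg <- c(msg, "pixelSizeUm must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct a TimeLapseStack
#'
#' @param frames numeric 3-D array `(time, y, x)`.
#' @param frameIntervalS seconds between consecutive frames.
#' @param pixelSizeUm micrometers per pixel.
#' @param originName field-of-view label.
#' @return A [TimeLapseStack-class] object.
#' @export
TimeLapseStack <- function(frames, frameIntervalS, pixelSizeUm,
                           originName = "stack") {
  new("TimeLapseStack", frames = frames,
      frameIntervalS = as.numeric(frameIntervalS),
      pixelSizeUm = as.numeric(pixelSizeUm),
      originName = as.character(originName))
}

#' @describeIn TimeLapseStack the raw frame array `(time, y, x)`.
#' @param x,object a `TimeLapseStack`.
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @export
setMethod("frames", "TimeLapseStack", function(x) x@frames)

#' @describeIn TimeLapseStack seconds per frame.
#' @export
setGeneric("frameIntervalS", function(x) standardGeneric("frameIntervalS"))

#' @export
setMethod("frameIntervalS", "TimeLapseStack", function(x) x@frameIntervalS)

#' @describeIn TimeLapseStack micrometers per pixel.
#' @export
setGeneric("pixelSizeUm", function(x) standardGeneric("pixelSizeUm"))

#' @export
setMethod("pixelSizeUm", "TimeLapseStack", function(x) x@pixelSizeUm)

#' @describeIn TimeLapseStack field-of-view label.
#' @export
setGeneric("originName", function(x) standardGeneric("originName"))

#' @export
setMethod("originName", "TimeLapseStack", function(x) x@originName)

#' @describeIn TimeLapseStack number of frames.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @export
setMethod("nFrames", "TimeLapseStack", function(x) dim(x@frames)[1])

#' @describeIn TimeLapseStack acquisition times in minutes from frame 0.
#' @export
setGeneric("frameTimesMin", function(x) standardGeneric("frameTimesMin"))

#' @export
setMethod("frameTimesMin", "TimeLapseStack", function(x)
  (seq_len(dim(x@frames)[1]) - 1) * x@frameIntervalS / 60)

#' @export
setMethod("dim", "TimeLapseStack", function(x) dim(x@frames))

#' Extract a single frame as a (y, x) matrix
#'
#' @param x a `TimeLapseStack`.
#' @param i 1-based frame index.
#' @return numeric matrix (y rows, x columns).
#' @export
getFrame <- function(x, i) {
  stopifnot(is(x, "TimeLapseStack"), i >= 1, i <= nFrames(x))
  d <- dim(x@frames)
  matrix(x@frames[i, , ], nrow = d[2], ncol = d[3])
}

setMethod("show", "TimeLapseStack", function(object) {
  d <- dim(object@frames)
  cat("TimeLapseStack '", object@originName, "': ",
      d[1], " frames of ", d[2], "x", d[3], " px, ",
      object@frameIntervalS, " s/frame (",
      format(round((d[1] - 1) * object@frameIntervalS / 60, 1)), " min), ",
      object@pixelSizeUm, " um/px\n", sep = "")
})

# ---- RunConfig --------------------------------------------------------------

#' RunConfig: tunable parameters of the analysis pipeline
#'
#' Thresholds and tolerances used by detection, event timing, tracking and
#' fitting. Thresholds left `NA` are resolved automatically per stack
#' (see [resolveConfig()]): `brightThreshold` falls back to Otsu's method on
#' frame 0, `darkThreshold` to halfway between the frame-0 background median
#' and the bright threshold, `colonyDelta` (foreground |frame - background|
#' cutoff of colony segmentation) to half the spore contrast.
#'
#' @slot brightThreshold intensity above which a frame-0 pixel is
#'   phase-bright; `NA` = Otsu on frame 0.
#' @slot darkThreshold intensity under which a spore center counts as
#'   phase-dark (germinated); `NA` = auto; must be < `brightThreshold`.
#' @slot centerRadiusPx radius (px) of the center disk averaged for the
#'   intensity trace.
#' @slot minSporeAreaPx,maxSporeAreaPx area filter (px) for frame-0 detection.
#' @slot settleTolerance intensity tolerance defining the settled pre/post
#'   plateaus of a germination trace.
#' @slot burstJumpFraction minimal relative single-frame area jump reported
#'   as a coat burst (> 0).
#' @slot fitMinR minimal |r| of an accepted log2(area) fit window, in (0, 1].
#' @slot collisionMarginPx dilation margin (px) used for the touch test that
#'   censors area tracking.
#' @slot colonyDelta |frame - background| threshold of colony segmentation;
#'   `NA` = auto.
#' @slot divisionMaxErosion maximal erosion depth tried when looking for a
#'   two-object split at first division.
#' @slot randomSeed seed governing any randomness of a run.
#' @export
setClass("RunConfig",
  representation(
    brightThreshold = "numeric",
    darkThreshold = "numeric",
    centerRadiusPx = "numeric",
    minSporeAreaPx = "numeric",
    maxSporeAreaPx = "numeric",
    settleTolerance = "numeric",
    burstJumpFraction = "numeric",
    fitMinR = "numeric",
    collisionMarginPx = "numeric",
    colonyDelta = "numeric",
    divisionMaxErosion = "numeric",
    randomSeed = "numeric"
  )
)

setValidity("RunConfig", function(object) {
  msg <- character(0)
  if (is.finite(object@brightThreshold) && is.finite(object@darkThreshold) &&
      object@darkThreshold >= object@brightThreshold)
    msg <- c(msg, "darkThreshold must be below brightThreshold")
  if (object@burstJumpFraction <= 0)
    msg <- c(msg, "burstJumpFraction must be > 0")
  if (object@fitMinR <= 0 || object@fitMinR > 1)
    msg <- c(msg, "fitMinR must be in (0, 1]")
  if (object@minSporeAreaPx < 1 || object@maxSporeAreaPx < object@minSporeAreaPx)
    msg <- c(msg, "need 1 <= minSporeAreaPx <= maxSporeAreaPx")
  if (object@centerRadiusPx < 0)
    msg <- c(msg, "centerRadiusPx must be >= 0")
  if (object@collisionMarginPx < 0)
    msg <- c(msg, "collisionMarginPx must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Build a RunConfig
#'
#' All arguments have headless-runnable defaults; thresholds default to `NA`
#' meaning per-stack automatic resolution. See [RunConfig-class] for the
#' meaning and units of each parameter.
#'
#' @param brightThreshold,darkThreshold,centerRadiusPx,minSporeAreaPx,maxSporeAreaPx,settleTolerance,burstJumpFraction,fitMinR,collisionMarginPx,colonyDelta,divisionMaxErosion,randomSeed see [RunConfig-class].
#' @return A validated [RunConfig-class] object.
#' @examples
#' cfg <- runConfig(darkThreshold = 60)
#' cfg
#' @export
runConfig <- function(brightThreshold = NA_real_,
                      darkThreshold = NA_real_,
                      centerRadiusPx = 2,
                      minSporeAreaPx = 5,
                      maxSporeAreaPx = 2000,
                      settleTolerance = 4,
                      burstJumpFraction = 0.2,
                      fitMinR = 0.99,
                      collisionMarginPx = 2,
                      colonyDelta = NA_real_,
                      divisionMaxErosion = 6,
                      randomSeed = 1) {
  new("RunConfig",
      brightThreshold = as.numeric(brightThreshold),
      darkThreshold = as.numeric(darkThreshold),
      centerRadiusPx = as.numeric(centerRadiusPx),
      minSporeAreaPx = as.numeric(minSporeAreaPx),
      maxSporeAreaPx = as.numeric(maxSporeAreaPx),
      settleTolerance = as.numeric(settleTolerance),
      burstJumpFraction = as.numeric(burstJumpFraction),
      fitMinR = as.numeric(fitMinR),
      collisionMarginPx = as.numeric(collisionMarginPx),
      colonyDelta = as.numeric(colonyDelta),
      divisionMaxErosion = as.numeric(divisionMaxErosion),
      randomSeed = as.numeric(randomSeed))
}

setMethod("show", "RunConfig", function(object) {
  cat("RunConfig:\n")
  for (s in slotNames(object)) {
    cat("  ", s, " = ", format(slot(object, s)), "\n", sep = "")
  }
})

# ---- AreaTrace --------------------------------------------------------------

#' AreaTrace: per-frame colony area of one tracked spore
#'
#' Produced by [trackAreas()]. Holds the measured colony area per frame up to
#' (but excluding) the censoring frame, the censoring time and reason, and
#' the per-frame pixel footprints needed by division detection.
#'
#' Censoring reasons: `touch_colony` (the dilated component touched another
#' segmented object), `touch_boundary` (it touched the image border),
#' `end_of_movie` (tracked to the last frame), `lost` (the component
#' vanished, e.g. lysis or defocus).
#'
#' @slot sporeId integer spore identifier.
#' @slot timesMin acquisition times (minutes) of the retained frames.
#' @slot areasPx2 areas in pixels.
#' @slot areasUm2 areas in square micrometers.
#' @slot censoredAtMin time (minutes) of the censoring frame, `NA` if the
#'   trace runs to the end of the movie.
#' @slot censorReason one of `touch_colony`, `touch_boundary`,
#'   `end_of_movie`, `lost`.
#' @slot footprints list of integer vectors: linear pixel indices of the
#'   tracked component in each retained frame.
#' @slot imageDim `(ny, nx)` of the source frames.
#' @export
setClass("AreaTrace",
  representation(
    sporeId = "integer",
    timesMin = "numeric",
    areasPx2 = "numeric",
    areasUm2 = "numeric",
    censoredAtMin = "numeric",
    censorReason = "character",
    footprints = "list",
    imageDim = "integer"
  )
)

setValidity("AreaTrace", function(object) {
  msg <- character(0)
  n <- length(object@timesMin)
  if (length(object@areasPx2) != n || length(object@areasUm2) != n ||
      length(object@footprints) != n)
    msg <- c(msg, "times, areas and footprints must have equal length")
  if (n > 1 && any(diff(object@timesMin) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (any(object@areasPx2 <= 0))
    msg <- c(msg, "areas must be positive where defined")
  if (!object@censorReason %in%
      c("touch_colony", "touch_boundary", "end_of_movie", "lost"))
    msg <- c(msg, "unknown censorReason")
  if (is.finite(object@censoredAtMin) && n > 0 &&
      any(object@timesMin >= object@censoredAtMin))
    msg <- c(msg, "no trace values at or after the censoring time")
  if (length(msg)) msg else TRUE
})

#' @describeIn AreaTrace data.frame view `(time_min, area_px2, area_um2)`.
#' @param x an `AreaTrace`.
#' @export
setGeneric("areaTable", function(x) standardGeneric("areaTable"))

#' @export
setMethod("areaTable", "AreaTrace", function(x)
  data.frame(spore_id = x@sporeId, time_min = x@timesMin,
             area_px2 = x@areasPx2, area_um2 = x@areasUm2))

#' @describeIn AreaTrace censoring time in minutes (`NA` = uncensored).
#' @export
setGeneric("censoredAtMin", function(x) standardGeneric("censoredAtMin"))

#' @export
setMethod("censoredAtMin", "AreaTrace", function(x) x@censoredAtMin)

#' @describeIn AreaTrace censoring reason.
#' @export
setGeneric("censorReason", function(x) standardGeneric("censorReason"))

#' @export
setMethod("censorReason", "AreaTrace", function(x) x@censorReason)

setMethod("show", "AreaTrace", function(object) {
  n <- length(object@timesMin)
  cat("AreaTrace spore ", object@sporeId, ": ", n, " frames",
      if (n) paste0(" [", format(round(min(object@timesMin), 2)), ", ",
                    format(round(max(object@timesMin), 2)), "] min"),
      ", censor: ", object@censorReason,
      if (is.finite(object@censoredAtMin))
        paste0(" at ", format(round(object@censoredAtMin, 2)), " min"),
      "\n", sep = "")
})
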