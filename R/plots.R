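# Static diagnostic plots: intensity-vs-time and log2(area)-vs-time
# overlays (one page per spore plus a superimposed overview page, the
# layout the dual-plot navigation of the original macro is replaced by),
# and frequency histograms of the four timing metrics.

#' Overlay plot of center-intensity traces
#'
#' First page: all traces superimposed; following pages: one trace per
#' spore with the 90%/10% crossing marks when an event is supplied.
#'
#' @param traces list of trace data.frames from [extractTrace()].
#' @param path output PDF path.
#' @param events optional data.frame of [detectGermination()] rows.
#' @return `path`, invisibly.
#' @export
plotIntensityTraces <- function(traces, path, events = NULL) {
  traces <- traces[!vapply(traces, is.null, logical(1))]
  if (!length(traces)) return(invisible(path))
  grDevices::pdf(path, width = 7, height = 5)
  on.exit(grDevices::dev.off())
  xr <- range(unlist(lapply(traces, `[[`, "time_min")))
  yr <- range(unlist(lapply(traces, `[[`, "intensity")))
  graphics::plot(NA, xlim = xr, ylim = yr, xlab = "time (min)",
                 ylab = "center intensity", main = "all spores")
  for (tr in traces)
    graphics::lines(tr$time_min, tr$intensity,
                    col = grDevices::adjustcolor("darkgreen", 0.4))
  for (tr in traces) {
    id <- tr$spore_id[1]
    graphics::plot(tr$time_min, tr$intensity, type = "l",
                   xlab = "time (min)", ylab = "center intensity",
                   main = paste("spore", id))
    if (!is.null(events)) {
      ev <- events[events$spore_id == id & events$detected, , drop = FALSE]
      if (nrow(ev)) {
        graphics::points(c(ev$t_start_min, ev$t_end_min),
                         c(ev$i_post + 0.9 * ev$drop_range,
                           ev$i_post + 0.1 * ev$drop_range),
                         col = "red", cex = 1.2)
      }
    }
  }
  invisible(path)
}

#' Overlay plot of log2(area) traces
#'
#' @param areaTraces list of [AreaTrace-class] objects.
#' @param path output PDF path.
#' @return `path`, invisibly.
#' @export
plotAreaTraces <- function(areaTraces, path) {
  areaTraces <- areaTraces[!vapply(areaTraces, is.null, logical(1))]
  areaTraces <- areaTraces[vapply(areaTraces, function(a)
    length(a@timesMin) > 0, logical(1))]
  if (!length(areaTraces)) return(invisible(path))
  grDevices::pdf(path, width = 7, height = 5)
  on.exit(grDevices::dev.off())
  xr <- range(unlist(lapply(areaTraces, function(a) a@timesMin)))
  yr <- range(unlist(lapply(areaTraces, function(a) log2(a@areasPx2))))
  graphics::plot(NA, xlim = xr, ylim = yr, xlab = "time (min)",
                 ylab = "log2 area (px)", main = "all colonies")
  for (a in areaTraces)
    graphics::lines(a@timesMin, log2(a@areasPx2),
                    col = grDevices::adjustcolor("steelblue", 0.4))
  invisible(path)
}

#' Frequency histograms of the timing metrics
#'
#' One panel per metric (start of germination, germination time, outgrowth
#' time, generation time), conditions overlaid; Freedman-Diaconis binning
#' by default.
#'
#' @param records record data.frame.
#' @param path output PDF path.
#' @param breaks histogram breaks rule (default `"FD"`).
#' @return `path`, invisibly.
#' @export
plotMetricHistograms <- function(records, path, breaks = "FD") {
  grDevices::pdf(path, width = 8, height = 6)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(2, 2))
  conds <- unique(records$condition)
  cols <- grDevices::adjustcolor(c("darkgreen", "red", "blue", "orange"),
                                 0.5)
  for (mn in names(.TIMING_METRICS)) {
    col <- .TIMING_METRICS[[mn]]
    vals <- records[[col]][is.finite(records[[col]])]
    if (length(vals) < 2) {
      graphics::plot.new(); graphics::title(main = paste(mn, "(no data)"))
      next
    }
    br <- if (identical(breaks, "FD") && length(vals) >= 3) {
      nb <- nclass.FD(vals)
      seq(min(vals), max(vals), length.out = max(nb, 2) + 1)
    } else breaks
    first <- TRUE
    for (j in seq_along(conds)) {
      v <- records[[col]][records$condition == conds[j] &
                            is.finite(records[[col]])]
      if (length(v) < 2) next
      graphics::hist(v, breaks = br, col = cols[(j - 1) %% 4 + 1],
                     main = if (first) mn else NULL, xlab = "min",
                     add = !first)
      first <- FALSE
    }
  }
  invisible(path)
}
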