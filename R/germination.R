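# Step 2: center-intensity traces and the bright->dark germination event.
# The event is timed by the 90%/10% crossings of the drop range (the
# difference between the settled pre- and post-transition intensities), each
# refined by linear interpolation between the bracketing frames.

#' Extract the center-intensity trace of one marker
#'
#' Mean intensity over a disk of `centerRadiusPx` around the marker centroid,
#' one value per frame; times in minutes from frame 0. A center disk clipped
#' by the image boundary is an error (such markers should be excluded).
#'
#' @param stack a [TimeLapseStack-class].
#' @param marker one-row marker data.frame (from [detectSpores()]).
#' @param centerRadiusPx disk radius; defaults to the config default (2 px).
#' @return data.frame `spore_id, time_min, intensity`.
#' @export
extractTrace <- function(stack, marker, centerRadiusPx = 2) {
  stopifnot(is(stack, "TimeLapseStack"), nrow(marker) == 1)
  d <- dim(stack@frames)
  ny <- d[2]; nx <- d[3]
  cy <- marker$centroid_y; cx <- marker$centroid_x; r <- centerRadiusPx
  if (cy - r < 0 || cy + r > ny - 1 || cx - r < 0 || cx + r > nx - 1)
    stop("center region of spore ", marker$spore_id,
         " is clipped by the image boundary; exclude this marker")
  idx <- .disk_indices(cy, cx, r, ny, nx)
  nt <- d[1]
  ys <- (idx - 1) %% ny + 1
  xs <- (idx - 1) %/% ny + 1
  k <- length(idx)
  sub <- stack@frames[cbind(rep(seq_len(nt), k),
                            rep(ys, each = nt), rep(xs, each = nt))]
  vals <- rowMeans(matrix(sub, nrow = nt))
  data.frame(spore_id = marker$spore_id, time_min = frameTimesMin(stack),
             intensity = vals)
}

# settled plateau estimation (two-pass):
#  pre:  i_pre_estimate = median of first 5 frames; pre-plateau = frames
#        before the first frame below (estimate - settleTolerance)
#  post: frames from the first frame within settleTolerance of the trace
#        minimum, up to 10 frames
.plateaus <- function(vals, tol) {
  n <- length(vals)
  est <- median(vals[seq_len(min(5, n))])
  drop_idx <- which(vals < est - tol)[1]
  pre_idx <- if (is.na(drop_idx) || drop_idx == 1) 1L else seq_len(drop_idx - 1)
  minv <- min(vals)
  settle_idx <- which(vals <= minv + tol)[1]
  post_idx <- settle_idx:min(settle_idx + 9, n)
  list(i_pre = median(vals[pre_idx]), i_post = median(vals[post_idx]),
       first_drop = drop_idx)
}

# last down-crossing of `level` with segment start <= before_idx, or first
# down-crossing with segment start >= from_idx; linear interpolation
.down_crossings <- function(times, vals, level) {
  n <- length(vals)
  k <- which(vals[-n] >= level & vals[-1] < level)
  if (!length(k)) return(NULL)
  tcross <- times[k] + (vals[k] - level) / (vals[k] - vals[k + 1]) *
    (times[k + 1] - times[k])
  data.frame(seg = k, t = tcross)
}

#' Detect the germination event in a center-intensity trace
#'
#' A spore counts as germinating when its center intensity falls below the
#' dark threshold. The settled pre- and post-transition intensities are
#' plateau medians; their difference is the drop range. The start of
#' germination is the last down-crossing of the 90% drop-range level before
#' the transition midpoint (50% level), the end is the first down-crossing
#' of the 10% level after it, both linearly interpolated between bracketing
#' frames; the germination time is their difference. A spore already
#' phase-dark at frame 0 is flagged `pre_germinated` and carries no timing.
#' Traces with several large drops use the first sustained one, with a
#' warning.
#'
#' @param trace data.frame from [extractTrace()].
#' @param config a [RunConfig-class]; `darkThreshold` must be resolved
#'   (finite), see [resolveConfig()].
#' @return one-row data.frame: `spore_id, detected, pre_germinated, i_pre,
#'   i_post, drop_range, t_start_min, t_end_min, duration_min`.
#' @export
detectGermination <- function(trace, config = runConfig(darkThreshold = 60)) {
  stopifnot(is.data.frame(trace), nrow(trace) >= 2, is(config, "RunConfig"))
  if (any(diff(trace$time_min) <= 0)) stop("trace times must be increasing")
  dark <- config@darkThreshold
  if (!is.finite(dark))
    stop("darkThreshold is NA; resolve the config against a stack first")
  vals <- trace$intensity
  times <- trace$time_min
  id <- trace$spore_id[1]
  none <- data.frame(spore_id = id, detected = FALSE, pre_germinated = FALSE,
                     i_pre = NA_real_, i_post = NA_real_,
                     drop_range = NA_real_, t_start_min = NA_real_,
                     t_end_min = NA_real_, duration_min = NA_real_)
  pl <- .plateaus(vals, config@settleTolerance)
  if (pl$i_pre < dark) {  # phase-dark from the start
    none$pre_germinated <- TRUE
    none$i_pre <- pl$i_pre
    return(none)
  }
  if (min(vals) >= dark) return(none)
  drop <- pl$i_pre - pl$i_post
  if (drop <= 0) return(none)
  l90 <- pl$i_post + 0.9 * drop
  l50 <- pl$i_post + 0.5 * drop
  l10 <- pl$i_post + 0.1 * drop
  c50 <- .down_crossings(times, vals, l50)
  c90 <- .down_crossings(times, vals, l90)
  c10 <- .down_crossings(times, vals, l10)
  if (is.null(c50) || is.null(c90) || is.null(c10)) return(none)
  mid_seg <- c50$seg[1]
  cand90 <- c90[c90$seg <= mid_seg, , drop = FALSE]
  t_start <- if (nrow(cand90)) cand90$t[nrow(cand90)] else c90$t[1]
  cand10 <- c10[c10$seg >= mid_seg, , drop = FALSE]
  t_end <- if (nrow(cand10)) cand10$t[1] else c10$t[nrow(c10)]
  if (nrow(c50) > 1 || any(vals[-seq_len(c10$seg[1])] > l50))
    warning("spore ", id, ": non-monotone trace with multiple drops; ",
            "using the first sustained drop")
  if (t_end <= t_start) return(none)
  data.frame(spore_id = id, detected = TRUE, pre_germinated = FALSE,
             i_pre = pl$i_pre, i_post = pl$i_post, drop_range = drop,
             t_start_min = t_start, t_end_min = t_end,
             duration_min = t_end - t_start)
}

#' Collect germination timing vectors of a population
#'
#' Returns the start-of-germination and germination-time vectors of the
#' detected events only (pre-germinated and undetected spores excluded);
#' these are the inputs of the population statistics.
#'
#' @param events data.frame of rows from [detectGermination()].
#' @return list with numeric vectors `t_start_min` and `duration_min`.
#' @export
summarizeGermination <- function(events) {
  if (is.null(events) || !nrow(events))
    return(list(t_start_min = numeric(0), duration_min = numeric(0)))
  ok <- events$detected & !events$pre_germinated
  list(t_start_min = events$t_start_min[ok],
       duration_min = events$duration_min[ok])
}
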