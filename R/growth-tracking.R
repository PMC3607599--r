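# Step 3: colony contour/area in time with censoring at collisions, plus
# first-division and coat-burst detection.
#
# Segmentation contract: per frame, foreground = |frame - background| above
# colonyDelta (background = per-frame median intensity), 8-connected
# components; a marker's component is found by seeding at its centroid in
# frame 0 and by maximal pixel overlap with the previous footprint
# afterwards. The trace is censored (half-open: the censoring frame itself
# is excluded) at the first frame where the component dilated by
# collisionMarginPx overlaps foreign foreground or where it comes within
# collisionMarginPx of the image border.

#' Resolve automatic thresholds of a RunConfig against a stack
#'
#' Fills any `NA` thresholds: `brightThreshold` by Otsu's method on frame 0,
#' `darkThreshold` halfway between the frame-0 background median and the
#' bright threshold, `colonyDelta` as half of (brightThreshold - background).
#'
#' @param stack a [TimeLapseStack-class].
#' @param config a [RunConfig-class].
#' @return a fully-resolved [RunConfig-class].
#' @export
resolveConfig <- function(stack, config = runConfig()) {
  f0 <- getFrame(stack, 1)
  bg0 <- median(f0)
  if (!is.finite(config@brightThreshold))
    config@brightThreshold <- otsuThreshold(f0)
  # contrast between the segregated modes; |.| also covers stacks whose
  # frame-0 objects are darker than the background (vegetative mode)
  contrast <- abs(config@brightThreshold - bg0)
  if (!is.finite(config@darkThreshold))
    config@darkThreshold <- min(bg0, config@brightThreshold) - contrast / 2
  if (!is.finite(config@colonyDelta))
    config@colonyDelta <- contrast / 2
  validObject(config)
  config
}

.mode_label <- function(labs) {
  labs <- labs[labs > 0]
  if (!length(labs)) return(0L)
  tb <- tabulate(labs)
  which.max(tb)
}

#' Track colony areas of all included markers through the stack
#'
#' See the segmentation contract above. All markers are tracked in one pass
#' so that colony-colony contacts censor both parties; two markers mapping
#' onto one merged component are likewise censored as `touch_colony`.
#'
#' @param stack a [TimeLapseStack-class].
#' @param markers marker table from [detectSpores()] (or manual markers with
#'   columns `spore_id`, `centroid_y`, `centroid_x`, `included`).
#' @param config a [RunConfig-class] (auto-resolved against the stack).
#' @return named list of [AreaTrace-class] objects, one per included marker.
#' @export
trackAreas <- function(stack, markers, config = runConfig()) {
  stopifnot(is(stack, "TimeLapseStack"), is.data.frame(markers))
  cfg <- resolveConfig(stack, config)
  mk <- markers[markers$included, , drop = FALSE]
  d <- dim(stack@frames)
  nt <- d[1]; ny <- d[2]; nx <- d[3]
  times <- frameTimesMin(stack)
  margin <- as.integer(cfg@collisionMarginPx)
  nm <- nrow(mk)
  state <- vector("list", nm)
  for (i in seq_len(nm))
    state[[i]] <- list(active = TRUE, fp = integer(0),
                       times = numeric(0), areas = integer(0),
                       fps = list(), cens = NA_real_, reason = "end_of_movie",
                       coast_since = NA_real_)
  seed_idx <- as.integer(round(mk$centroid_y) + 1 +
                           round(mk$centroid_x) * ny)
  bg0 <- median(matrix(stack@frames[1, , ], ny, nx))
  for (f in seq_len(nt)) {
    if (!any(vapply(state, `[[`, logical(1), "active"))) break
    frame <- matrix(stack@frames[f, , ], ny, nx)
    # per-frame median absorbs slow illumination drift, but flips to the
    # colony intensity once colonies dominate the field; anchor to frame 0
    bg <- median(frame)
    if (abs(bg - bg0) > cfg@colonyDelta) bg <- bg0
    mask <- abs(frame - bg) > cfg@colonyDelta
    lab <- labelComponents(mask, 8)
    fg <- which(lab > 0)
    pix <- split(fg, lab[fg])
    sizes <- tabulate(lab[fg])
    chosen <- integer(nm)
    own_labels <- vector("list", nm)
    for (i in seq_len(nm)) {
      if (!state[[i]]$active) next
      l <- if (f == 1) {
        l0 <- lab[seed_idx[i]]
        if (l0 == 0) {  # search a small neighborhood around the seed
          r0 <- (seed_idx[i] - 1) %% ny; c0 <- (seed_idx[i] - 1) %/% ny
          box <- expand.grid(r = pmax(0, r0 - 2):pmin(ny - 1, r0 + 2),
                             c = pmax(0, c0 - 2):pmin(nx - 1, c0 + 2))
          l0 <- .mode_label(lab[box$r + 1 + box$c * ny])
        }
        l0
      } else {
        .mode_label(lab[state[[i]]$fp])
      }
      if (l == 0 && f > 1) {
        # a germinating spore can fade through background contrast between
        # the bright and dark phase: coast on the stale footprint and the
        # original seed, and re-acquire when the dark object reappears
        l <- lab[seed_idx[i]]
      }
      # all components touching the previous footprint are this spore's own
      # (a fading disk can fragment at the threshold); they are not treated
      # as foreign colonies in the collision test
      own_labels[[i]] <- if (f == 1) l else
        unique(c(l, lab[state[[i]]$fp]))
      chosen[i] <- l
      if (l == 0 && is.na(state[[i]]$coast_since))
        state[[i]]$coast_since <- times[f]
      if (l > 0) state[[i]]$coast_since <- NA_real_
    }
    dup <- chosen[chosen > 0][duplicated(chosen[chosen > 0])]
    for (i in seq_len(nm)) {
      if (!state[[i]]$active || chosen[i] == 0) next
      l <- chosen[i]
      fp <- pix[[as.character(l)]]
      rows <- (fp - 1) %% ny; cols <- (fp - 1) %/% ny  # 0-based
      touch_boundary <- margin > 0 &&
        any(rows < margin | rows > ny - 1 - margin |
            cols < margin | cols > nx - 1 - margin)
      touch_colony <- l %in% dup
      if (!touch_colony && margin > 0) {
        r0 <- max(0, min(rows) - margin); r1 <- min(ny - 1, max(rows) + margin)
        c0 <- max(0, min(cols) - margin); c1 <- min(nx - 1, max(cols) + margin)
        bh <- r1 - r0 + 1; bw <- c1 - c0 + 1
        own <- matrix(FALSE, bh, bw)
        own[(rows - r0) + 1 + (cols - c0) * bh] <- TRUE
        dil <- binaryDilate(own, margin)
        sub_lab <- lab[(r0 + 1):(r1 + 1), (c0 + 1):(c1 + 1), drop = FALSE]
        big <- sizes[pmax(sub_lab, 1L)] >= cfg@minSporeAreaPx
        foreign <- dil & sub_lab > 0 & big &
          !matrix(sub_lab %in% own_labels[[i]], nrow(sub_lab))
        touch_colony <- any(foreign)
      }
      if (touch_boundary || touch_colony) {
        state[[i]]$active <- FALSE
        state[[i]]$cens <- times[f]
        state[[i]]$reason <- if (touch_colony) "touch_colony" else
          "touch_boundary"
        next
      }
      state[[i]]$times <- c(state[[i]]$times, times[f])
      state[[i]]$areas <- c(state[[i]]$areas, length(fp))
      state[[i]]$fps[[length(state[[i]]$fps) + 1L]] <- fp
      state[[i]]$fp <- fp
    }
  }
  um2 <- stack@pixelSizeUm^2
  out <- vector("list", nm)
  for (i in seq_len(nm)) {
    st <- state[[i]]
    if (st$active && !is.na(st$coast_since)) {
      # vanished (lysis/defocus) and never re-acquired: truncated trace
      st$cens <- st$coast_since
      st$reason <- "lost"
    }
    out[[i]] <- new("AreaTrace", sporeId = as.integer(mk$spore_id[i]),
                    timesMin = st$times, areasPx2 = as.numeric(st$areas),
                    areasUm2 = as.numeric(st$areas) * um2,
                    censoredAtMin = st$cens, censorReason = st$reason,
                    footprints = st$fps, imageDim = c(ny, nx))
  }
  names(out) <- as.character(mk$spore_id)
  out
}

#' Track the colony area of a single marker
#'
#' Convenience wrapper around [trackAreas()]; collision censoring against
#' other markers requires passing the full marker table via `allMarkers`.
#'
#' @param stack a [TimeLapseStack-class].
#' @param marker one-row marker data.frame; must be included.
#' @param config a [RunConfig-class].
#' @param allMarkers full marker table (defaults to `marker` alone).
#' @return an [AreaTrace-class].
#' @export
trackArea <- function(stack, marker, config = runConfig(),
                      allMarkers = marker) {
  stopifnot(nrow(marker) == 1, isTRUE(marker$included))
  trackAreas(stack, allMarkers, config)[[as.character(marker$spore_id)]]
}

# does the footprint split into >= 2 sub-objects (each >= minArea px) under
# some erosion depth 1..maxDepth? ("watershed-style" split test)
.splits_under_erosion <- function(fp, ny, nx, minArea, maxDepth) {
  rows <- (fp - 1) %% ny; cols <- (fp - 1) %/% ny
  r0 <- min(rows); c0 <- min(cols)
  bh <- max(rows) - r0 + 1; bw <- max(cols) - c0 + 1
  sub <- matrix(FALSE, bh, bw)
  sub[(rows - r0) + 1 + (cols - c0) * bh] <- TRUE
  for (k in seq_len(maxDepth)) {
    sub <- binaryErode(sub, 1)
    if (!any(sub)) return(FALSE)
    lab <- labelComponents(sub, 8)
    sizes <- tabulate(lab[lab > 0])
    if (sum(sizes >= minArea) >= 2) return(TRUE)
  }
  FALSE
}

#' Detect the first cell division of a tracked colony
#'
#' Auto mode: the earliest frame at which the tracked component, split on
#' its shape by iterative erosion (a watershed-style neck cut), yields at
#' least two sub-objects each above `minSporeAreaPx`, persisting for two
#' consecutive frames. A manual override table takes precedence and is
#' returned verbatim with `source = "manual"`.
#'
#' @param stack a [TimeLapseStack-class] (kept in the signature for
#'   intensity-based refinements; the shape split uses the footprints).
#' @param areaTrace an [AreaTrace-class] from [trackAreas()].
#' @param marker one-row marker data.frame.
#' @param config a [RunConfig-class].
#' @param manualDivisions optional data.frame `(spore_id, t_division_min)`.
#' @return one-row data.frame `(spore_id, t_division_min, source)`, or
#'   `NULL` if no division is found.
#' @export
detectFirstDivision <- function(stack, areaTrace, marker,
                                config = runConfig(),
                                manualDivisions = NULL) {
  stopifnot(is(areaTrace, "AreaTrace"))
  id <- areaTrace@sporeId
  if (!is.null(manualDivisions) && id %in% manualDivisions$spore_id) {
    t_man <- manualDivisions$t_division_min[
      match(id, manualDivisions$spore_id)]
    if (t_man < 0) stop("manual division time must be >= 0")
    return(data.frame(spore_id = id, t_division_min = t_man,
                      source = "manual"))
  }
  n <- length(areaTrace@timesMin)
  if (n < 2) return(NULL)
  ny <- areaTrace@imageDim[1]; nx <- areaTrace@imageDim[2]
  minA <- config@minSporeAreaPx
  maxd <- as.integer(config@divisionMaxErosion)
  split_at <- logical(n)
  for (k in seq_len(n)) {
    split_at[k] <- .splits_under_erosion(areaTrace@footprints[[k]], ny, nx,
                                         minA, maxd)
    if (k >= 2 && split_at[k - 1] && split_at[k])
      return(data.frame(spore_id = id,
                        t_division_min = areaTrace@timesMin[k - 1],
                        source = "auto"))
  }
  NULL
}

#' Detect jump-like area increases (coat burst) during outgrowth
#'
#' Reports frames in the outgrowth window (end of germination, first
#' division] where the single-frame relative area increase is at least
#' `burstJumpFraction` and also exceeds the local growth trend (the median
#' frame-to-frame area ratio in a +/-5-frame window) by the same fraction.
#'
#' @param areaTrace an [AreaTrace-class].
#' @param germEvent one-row event from [detectGermination()]; must be
#'   detected.
#' @param divisionEvent one-row event from [detectFirstDivision()] or `NULL`
#'   (no window, no bursts).
#' @param config a [RunConfig-class].
#' @return data.frame `(spore_id, t_burst_min, relative_jump)`; zero rows if
#'   none.
#' @export
detectBurst <- function(areaTrace, germEvent, divisionEvent,
                        config = runConfig()) {
  stopifnot(is(areaTrace, "AreaTrace"))
  empty <- data.frame(spore_id = integer(0), t_burst_min = numeric(0),
                      relative_jump = numeric(0))
  if (is.null(germEvent) || !isTRUE(germEvent$detected))
    stop("burst detection needs a detected germination event")
  if (is.null(divisionEvent)) return(empty)
  t_ge <- germEvent$t_end_min
  t_div <- divisionEvent$t_division_min
  tt <- areaTrace@timesMin
  aa <- areaTrace@areasPx2
  n <- length(tt)
  if (n < 2) return(empty)
  ratio <- aa[-1] / aa[-n]          # ratio[k] between frames k and k+1
  hits <- integer(0); jumps <- numeric(0)
  for (k in seq_len(n - 1)) {
    if (!(tt[k] > t_ge && tt[k] <= t_div)) next
    r <- ratio[k] - 1
    if (r < config@burstJumpFraction) next
    nb <- setdiff(max(1, k - 5):min(n - 1, k + 5), k)
    m <- if (length(nb)) median(ratio[nb]) else 1
    if (ratio[k] / m - 1 >= config@burstJumpFraction) {
      hits <- c(hits, k)
      jumps <- c(jumps, r)
    }
  }
  if (!length(hits)) return(empty)
  data.frame(spore_id = areaTrace@sporeId, t_burst_min = tt[hits + 1],
             relative_jump = jumps)
}

#' Outgrowth time: first division minus end of germination
#'
#' @param germEvent one-row event from [detectGermination()].
#' @param divisionEvent one-row event from [detectFirstDivision()] or `NULL`.
#' @return minutes, or `NA` if either event is missing; a negative result
#'   (division before end of germination) is an error.
#' @export
outgrowthTime <- function(germEvent, divisionEvent) {
  if (is.null(germEvent) || is.null(divisionEvent)) return(NA_real_)
  if (!isTRUE(germEvent$detected) || !is.finite(germEvent$t_end_min) ||
      !is.finite(divisionEvent$t_division_min)) return(NA_real_)
  ot <- divisionEvent$t_division_min - germEvent$t_end_min
  if (ot < 0)
    stop("inconsistent annotations: first division (",
         divisionEvent$t_division_min, " min) precedes end of germination (",
         germEvent$t_end_min, " min)")
  ot
}
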