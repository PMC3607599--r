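# Step 1: detect all phase-bright spores in frame 0 and mark them.

#' Detect phase-bright spores in the first frame
#'
#' Pixels of frame 0 above the bright threshold (configured, or Otsu's
#' method on frame 0 when `NA`) are grouped into 8-connected components;
#' components within the configured area bounds become markers. Markers are
#' ordered deterministically by centroid (row, col). Touching spores are
#' kept as one marker (and censored later at collision); zero detections
#' return an empty table, not an error.
#'
#' @param stack a [TimeLapseStack-class].
#' @param config a [RunConfig-class].
#' @return data.frame with columns `spore_id`, `centroid_y`, `centroid_x`
#'   (0-based), `area_px`, `mean_intensity`, `included`.
#' @export
detectSpores <- function(stack, config = runConfig()) {
  stopifnot(is(stack, "TimeLapseStack"), is(config, "RunConfig"))
  f0 <- getFrame(stack, 1)
  thr <- config@brightThreshold
  auto <- !is.finite(thr)
  if (auto) thr <- otsuThreshold(f0)
  empty0 <- data.frame(spore_id = integer(0), centroid_y = numeric(0),
                       centroid_x = numeric(0), area_px = integer(0),
                       mean_intensity = numeric(0), included = logical(0))
  # automatic thresholding on a frame without a phase-bright mode would
  # split the background noise; require the threshold to clear the
  # background by more than 3 robust sds
  if (auto && (thr - median(f0)) <= 3 * mad(f0)) return(empty0)
  rng <- range(f0)
  if (thr < rng[1] || thr > rng[2])
    warning("bright threshold ", thr, " outside frame-0 intensity range [",
            round(rng[1], 2), ", ", round(rng[2], 2), "]")
  mask <- f0 > thr
  lab <- labelComponents(mask, 8)
  k <- max(lab)
  empty <- data.frame(spore_id = integer(0), centroid_y = numeric(0),
                      centroid_x = numeric(0), area_px = integer(0),
                      mean_intensity = numeric(0), included = logical(0))
  if (k == 0) return(empty)
  idx <- which(lab > 0)
  labs <- lab[idx]
  rows <- (idx - 1) %% nrow(f0)       # 0-based
  cols <- (idx - 1) %/% nrow(f0)
  area <- tabulate(labs, k)
  cy <- tapply(rows, labs, mean)
  cx <- tapply(cols, labs, mean)
  mi <- tapply(f0[idx], labs, mean)
  keep <- area >= config@minSporeAreaPx & area <= config@maxSporeAreaPx
  if (!any(keep)) return(empty)
  df <- data.frame(centroid_y = as.numeric(cy[keep]),
                   centroid_x = as.numeric(cx[keep]),
                   area_px = as.integer(area[keep]),
                   mean_intensity = as.numeric(mi[keep]))
  df <- df[order(df$centroid_y, df$centroid_x), , drop = FALSE]
  df <- data.frame(spore_id = seq_len(nrow(df)), df, included = TRUE,
                   row.names = NULL)
  df
}

#' Mark manually excluded spores
#'
#' Listed markers get `included = FALSE`; all other fields are untouched.
#' Unknown ids raise an error naming the id.
#'
#' @param markers marker table from [detectSpores()].
#' @param exclusions integer vector of spore ids (possibly empty), e.g. from
#'   [readExclusions()].
#' @return the marker table with updated `included`.
#' @export
applyExclusions <- function(markers, exclusions) {
  stopifnot(is.data.frame(markers))
  if (!length(exclusions)) return(markers)
  unknown <- setdiff(exclusions, markers$spore_id)
  if (length(unknown))
    stop("exclusion table names unknown spore id(s): ",
         paste(unknown, collapse = ", "))
  markers$included[markers$spore_id %in% exclusions] <- FALSE
  markers
}
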