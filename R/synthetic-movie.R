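# Forward simulator of phase-contrast-like spore movies. Dormant spores are
# bright disks on a mid-gray background; germination is a logistic
# center-intensity drop whose 90%->10% span equals the scripted duration by
# construction; outgrowth is a dark footprint growing exponentially in area
# (two-lobe geometry after first division); a coat burst is a persistent
# single-frame relative area jump. Gaussian pixel noise is added last.

# union area of two equal disks of radius a whose centers are 1.9*a apart
.LOBE_SEP_FACTOR <- 1.9
.LOBE_UNION_COEF <- 2 * pi - (2 * acos(.LOBE_SEP_FACTOR / 2) -
  (.LOBE_SEP_FACTOR / 2) * sqrt(4 - .LOBE_SEP_FACTOR^2))

.SCRIPT_COLS <- c("spore_id", "centroid_y", "centroid_x", "fate",
                  "t_germ_start_min", "germ_duration_min",
                  "t_first_division_min", "generation_time_min",
                  "burst_time_min", "burst_jump", "i_bright", "i_dark",
                  "spore_radius_px", "lobe_axis_deg")

.validate_scripts <- function(s) {
  miss <- setdiff(.SCRIPT_COLS, names(s))
  if (length(miss))
    stop("spore scripts missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(s$spore_id)) stop("duplicate spore_id in scripts")
  bad <- !s$fate %in% c("outgrow", "germinate_only", "dormant", "vegetative")
  if (any(bad)) stop("unknown fate: ", paste(unique(s$fate[bad]), collapse = ", "))
  germ <- s$fate %in% c("outgrow", "germinate_only")
  if (any(germ & (!is.finite(s$t_germ_start_min) | s$t_germ_start_min < 0)))
    stop("germinating spores need t_germ_start_min >= 0")
  if (any(germ & (!is.finite(s$germ_duration_min) | s$germ_duration_min <= 0)))
    stop("germinating spores need germ_duration_min > 0")
  if (any(s$i_dark >= s$i_bright))
    stop("need i_dark < i_bright")
  out <- s$fate == "outgrow"
  if (any(out & !is.finite(s$t_first_division_min)))
    stop("outgrowing spores need t_first_division_min")
  if (any(out & s$t_first_division_min <=
            s$t_germ_start_min + s$germ_duration_min))
    stop("t_first_division_min must exceed the end of germination")
  gt <- s$fate %in% c("outgrow", "vegetative")
  if (any(gt & (!is.finite(s$generation_time_min) | s$generation_time_min <= 0)))
    stop("growing spores/cells need generation_time_min > 0")
  invisible(s)
}

#' Build a table of per-spore simulation scripts
#'
#' Each row scripts one spore: its position, fate (`outgrow`,
#' `germinate_only`, `dormant`, or `vegetative` for a cell already growing at
#' t = 0), germination start/duration, first-division time, generation time,
#' optional coat-burst time and jump, and rendering intensities. Missing
#' timing fields default to `NA` (unused for the given fate).
#'
#' @param spore_id integer ids.
#' @param centroid_y,centroid_x 0-based pixel coordinates.
#' @param fate fate per spore.
#' @param t_germ_start_min,germ_duration_min germination timing (minutes).
#' @param t_first_division_min,generation_time_min outgrowth/growth timing.
#' @param burst_time_min,burst_jump coat-burst time (minutes) and relative
#'   area jump; `NA`/0 = no burst.
#' @param i_bright,i_dark phase-bright and phase-dark intensities.
#' @param spore_radius_px spore disk radius in pixels.
#' @param lobe_axis_deg orientation of the post-division two-lobe axis.
#' @return validated data.frame of scripts.
#' @export
sporeScripts <- function(spore_id, centroid_y, centroid_x, fate,
                         t_germ_start_min = NA_real_,
                         germ_duration_min = NA_real_,
                         t_first_division_min = NA_real_,
                         generation_time_min = NA_real_,
                         burst_time_min = NA_real_,
                         burst_jump = NA_real_,
                         i_bright = 180, i_dark = 40,
                         spore_radius_px = 6, lobe_axis_deg = 0) {
  s <- data.frame(spore_id = as.integer(spore_id),
                  centroid_y = centroid_y, centroid_x = centroid_x,
                  fate = as.character(fate),
                  t_germ_start_min = t_germ_start_min,
                  germ_duration_min = germ_duration_min,
                  t_first_division_min = t_first_division_min,
                  generation_time_min = generation_time_min,
                  burst_time_min = burst_time_min,
                  burst_jump = burst_jump,
                  i_bright = i_bright, i_dark = i_dark,
                  spore_radius_px = spore_radius_px,
                  lobe_axis_deg = lobe_axis_deg,
                  stringsAsFactors = FALSE)
  .validate_scripts(s)
  s
}

#' Ground-truth manifest for a simulated movie
#'
#' Bundles the spore scripts with the acquisition and rendering parameters.
#'
#' @param scripts data.frame from [sporeScripts()] or [randomSporeScripts()].
#' @param frameIntervalS seconds per frame (default 30, the acquisition rate
#'   the analysis is designed around).
#' @param pixelSizeUm micrometers per pixel (default 0.065, a 100x phase
#'   objective with a 6.45 um camera pixel).
#' @param backgroundIntensity mid-gray background level.
#' @param noiseSd Gaussian pixel-noise standard deviation.
#' @param minSeparationPx minimal pairwise centroid distance at t = 0.
#' @return list of class `GroundTruthManifest`.
#' @export
groundTruthManifest <- function(scripts, frameIntervalS = 30,
                                pixelSizeUm = 0.065,
                                backgroundIntensity = 100, noiseSd = 2,
                                minSeparationPx = 18) {
  .validate_scripts(scripts)
  structure(list(scripts = scripts,
                 frameIntervalS = frameIntervalS,
                 pixelSizeUm = pixelSizeUm,
                 backgroundIntensity = backgroundIntensity,
                 noiseSd = noiseSd,
                 minSeparationPx = minSeparationPx),
            class = "GroundTruthManifest")
}

#' @export
print.GroundTruthManifest <- function(x, ...) {
  cat("GroundTruthManifest:", nrow(x$scripts), "spores;",
      x$frameIntervalS, "s/frame;", "background", x$backgroundIntensity,
      "; noise sd", x$noiseSd, "\n")
  print(table(x$scripts$fate))
  invisible(x)
}

#' Scripted center intensity of a spore at given times
#'
#' The logistic bright-to-dark transition used by the simulator, centered at
#' `t_germ_start + duration/2` with scale `duration / (2 log 9)` so that the
#' 90% and 10% drop-range crossings fall exactly at `t_germ_start` and
#' `t_germ_start + duration`. Dormant spores return `i_bright`.
#'
#' @param script one-row script data.frame.
#' @param tMin times in minutes.
#' @return intensities at `tMin`.
#' @export
scriptedCenterIntensity <- function(script, tMin) {
  stopifnot(nrow(script) == 1)
  if (script$fate %in% c("dormant"))
    return(rep(script$i_bright, length(tMin)))
  if (script$fate == "vegetative")
    return(rep(script$i_dark, length(tMin)))
  dur <- script$germ_duration_min
  tmid <- script$t_germ_start_min + dur / 2
  sc <- dur / (2 * log(9))
  script$i_dark + (script$i_bright - script$i_dark) /
    (1 + exp((tMin - tmid) / sc))
}

#' Scripted colony area law of a spore at given times
#'
#' Spore disk area while (and before) germinating; after the end of
#' germination the footprint ramps linearly to twice the spore area at first
#' division and then doubles every generation time,
#' `area(t) = a0 * 2^((t - t_div) / generation_time)`; a scripted burst
#' multiplies the area by `1 + burst_jump` from the burst time on.
#' Vegetative cells grow as `a_cell * 2^(t / generation_time)` from t = 0.
#'
#' @param script one-row script data.frame.
#' @param tMin times in minutes.
#' @return areas in squared pixels (continuous law, before rasterization).
#' @export
scriptedArea <- function(script, tMin) {
  stopifnot(nrow(script) == 1)
  a_s <- pi * script$spore_radius_px^2
  if (script$fate == "vegetative")
    return(a_s * 2^(tMin / script$generation_time_min))
  if (script$fate %in% c("dormant", "germinate_only"))
    return(rep(a_s, length(tMin)))
  t_ge <- script$t_germ_start_min + script$germ_duration_min
  t_div <- script$t_first_division_min
  a0 <- 2 * a_s
  base <- ifelse(tMin <= t_ge, a_s,
          ifelse(tMin < t_div,
                 a_s + (a0 - a_s) * (tMin - t_ge) / (t_div - t_ge),
                 a0 * 2^((tMin - t_div) / script$generation_time_min)))
  j <- script$burst_jump
  if (is.finite(script$burst_time_min) && is.finite(j) && j > 0)
    base <- base * ifelse(tMin >= script$burst_time_min, 1 + j, 1)
  base
}

# render one spore into frame matrix `img` at time t (min); returns img
.render_spore <- function(img, script, t) {
  ny <- nrow(img); nx <- ncol(img)
  cy <- script$centroid_y; cx <- script$centroid_x
  fate <- script$fate
  if (fate == "dormant") {
    idx <- .disk_indices(cy, cx, script$spore_radius_px, ny, nx)
    img[idx] <- script$i_bright
    return(img)
  }
  if (fate == "vegetative") {
    r <- sqrt(scriptedArea(script, t) / pi)
    idx <- .disk_indices(cy, cx, r, ny, nx)
    img[idx] <- script$i_dark
    return(img)
  }
  t_ge <- script$t_germ_start_min + script$germ_duration_min
  if (fate == "germinate_only" || t <= t_ge) {
    idx <- .disk_indices(cy, cx, script$spore_radius_px, ny, nx)
    img[idx] <- scriptedCenterIntensity(script, t)
    return(img)
  }
  # outgrowing, past end of germination: dark footprint following the law
  A <- scriptedArea(script, t)
  if (t < script$t_first_division_min) {
    idx <- .disk_indices(cy, cx, sqrt(A / pi), ny, nx)
  } else {
    ra <- sqrt(A / .LOBE_UNION_COEF)
    th <- script$lobe_axis_deg * pi / 180
    dy <- (.LOBE_SEP_FACTOR / 2) * ra * sin(th)
    dx <- (.LOBE_SEP_FACTOR / 2) * ra * cos(th)
    idx <- c(.disk_indices(cy + dy, cx + dx, ra, ny, nx),
             .disk_indices(cy - dy, cx - dx, ra, ny, nx))
  }
  img[idx] <- script$i_dark
  img
}

#' Simulate a phase-contrast-like time-lapse movie
#'
#' Deterministic for a fixed seed. Each spore is rendered per frame from its
#' script (see [scriptedCenterIntensity()] and [scriptedArea()] for the
#' closed-form laws the rendering follows); Gaussian pixel noise of standard
#' deviation `manifest$noiseSd` is added last.
#'
#' @param manifest a [groundTruthManifest()].
#' @param nFrames number of frames (>= 2).
#' @param shape `(ny, nx)` image size in pixels.
#' @param seed integer seed for the pixel noise.
#' @return A [TimeLapseStack-class].
#' @export
simulateMovie <- function(manifest, nFrames, shape, seed = 1) {
  stopifnot(inherits(manifest, "GroundTruthManifest"), nFrames >= 2,
            length(shape) == 2)
  s <- manifest$scripts
  ny <- shape[1]; nx <- shape[2]
  if (nrow(s)) {
    if (any(s$centroid_y < 0 | s$centroid_y > ny - 1 |
            s$centroid_x < 0 | s$centroid_x > nx - 1))
      stop("spore centroid outside image shape")
    if (nrow(s) > 1) {
      d <- as.matrix(dist(cbind(s$centroid_y, s$centroid_x)))
      diag(d) <- Inf
      if (min(d) < manifest$minSeparationPx)
        stop("overlapping initial spores: minimal centroid separation ",
             round(min(d), 1), " px is below ", manifest$minSeparationPx)
    }
  }
  times <- (seq_len(nFrames) - 1) * manifest$frameIntervalS / 60
  arr <- array(0, c(nFrames, ny, nx))
  for (f in seq_len(nFrames)) {
    img <- matrix(manifest$backgroundIntensity, ny, nx)
    for (i in seq_len(nrow(s)))
      img <- .render_spore(img, s[i, , drop = FALSE], times[f])
    arr[f, , ] <- img
  }
  if (manifest$noiseSd > 0) {
    old_seed <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    set.seed(seed)
    arr <- arr + array(rnorm(length(arr), 0, manifest$noiseSd), dim(arr))
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  }
  TimeLapseStack(arr, manifest$frameIntervalS, manifest$pixelSizeUm,
                 originName = "simulated")
}

#' Draw a random spore population script
#'
#' Spores are placed on a jittered grid with guaranteed minimal separation
#' and assigned fates by exact counts (`round(n * fraction)`), so the
#' population fractions are scripted, not sampled. Timing draws follow the
#' population parameters: lognormal start of germination (matched to the
#' given mean/sd), normal germination duration (truncated at 0.5 min),
#' normal outgrowth time and normal generation time (both truncated at 5
#' min).
#'
#' @param n number of spores.
#' @param shape `(ny, nx)` image size the spores must fit in.
#' @param params population parameter list, see [sporePopulationDefaults()].
#' @param seed integer seed.
#' @param spacingPx grid spacing (also the guaranteed separation).
#' @param marginPx margin kept free around the image border.
#' @return data.frame of scripts (see [sporeScripts()]).
#' @export
randomSporeScripts <- function(n, shape, params = sporePopulationDefaults(),
                               seed = 1, spacingPx = 36, marginPx = 20) {
  set.seed(seed)
  ny <- shape[1]; nx <- shape[2]
  gy <- floor((ny - 2 * marginPx) / spacingPx) + 1
  gx <- floor((nx - 2 * marginPx) / spacingPx) + 1
  if (gy * gx < n)
    stop("image shape too small for ", n, " spores at spacing ", spacingPx)
  cells <- expand.grid(gy = seq_len(gy) - 1, gx = seq_len(gx) - 1)
  cells <- cells[sample(nrow(cells), n), , drop = FALSE]
  jit <- spacingPx * 0.12
  cy <- marginPx + cells$gy * spacingPx + runif(n, -jit, jit)
  cx <- marginPx + cells$gx * spacingPx + runif(n, -jit, jit)
  nGerm <- round(n * params$frac_germinated)
  nOut <- round(n * params$frac_outgrown)
  if (nOut > nGerm) stop("frac_outgrown cannot exceed frac_germinated")
  fate <- rep("dormant", n)
  if (nGerm > 0) fate[seq_len(nGerm)] <- "germinate_only"
  if (nOut > 0) fate[seq_len(nOut)] <- "outgrow"
  # lognormal start matched to mean m, sd s
  m <- params$start_mean_min; s <- params$start_sd_min
  sdlog <- sqrt(log(1 + (s / m)^2))
  meanlog <- log(m) - sdlog^2 / 2
  t0 <- rlnorm(n, meanlog, sdlog)
  dur <- pmax(0.5, rnorm(n, params$duration_mean_min, params$duration_sd_min))
  outg <- pmax(5, rnorm(n, params$outgrowth_mean_min, params$outgrowth_sd_min))
  gen <- pmax(5, rnorm(n, params$generation_mean_min, params$generation_sd_min))
  germ <- fate %in% c("outgrow", "germinate_only")
  out <- fate == "outgrow"
  sporeScripts(
    spore_id = seq_len(n), centroid_y = cy, centroid_x = cx, fate = fate,
    t_germ_start_min = ifelse(germ, t0, NA_real_),
    germ_duration_min = ifelse(germ, dur, NA_real_),
    t_first_division_min = ifelse(out, t0 + dur + outg, NA_real_),
    generation_time_min = ifelse(out, gen, NA_real_),
    burst_time_min = NA_real_, burst_jump = NA_real_,
    i_bright = params$i_bright, i_dark = params$i_dark,
    spore_radius_px = params$spore_radius_px,
    lobe_axis_deg = runif(n, 0, 180))
}

#' Population parameters of the two reference conditions
#'
#' The stated world the simulator emulates: an untreated (`control`)
#' population in which 94.0% of spores germinate and 84.7% grow out, with
#' start of germination 63 +/- 56 min, germination time 3.5 +/- 0.9 min,
#' outgrowth time 254 +/- 34 min and generation time 62 +/- 14 min; and a
#' wet-heat-stressed population (`stress`, 85 C for 10 min) with 52.9% / 36.3%
#' fractions, start 82 +/- 68 min, germination time 5.3 +/- 1.7 min,
#' outgrowth 263 +/- 34 min, generation 62 +/- 13 min.
#'
#' @param condition `"control"` or `"stress"`.
#' @return named list of population parameters.
#' @export
sporePopulationDefaults <- function(condition = c("control", "stress")) {
  condition <- match.arg(condition)
  base <- list(i_bright = 180, i_dark = 40, spore_radius_px = 6)
  if (condition == "control") {
    c(base, list(frac_germinated = 0.940, frac_outgrown = 0.847,
                 start_mean_min = 63, start_sd_min = 56,
                 duration_mean_min = 3.5, duration_sd_min = 0.9,
                 outgrowth_mean_min = 254, outgrowth_sd_min = 34,
                 generation_mean_min = 62, generation_sd_min = 14))
  } else {
    c(base, list(frac_germinated = 0.529, frac_outgrown = 0.363,
                 start_mean_min = 82, start_sd_min = 68,
                 duration_mean_min = 5.3, duration_sd_min = 1.7,
                 outgrowth_mean_min = 263, outgrowth_sd_min = 34,
                 generation_mean_min = 62, generation_sd_min = 13))
  }
}

#' Write / read a ground-truth manifest
#'
#' A single text file: flat `# key: value` header lines for the
#' manifest-level parameters followed by the script table as CSV.
#'
#' @param manifest a [groundTruthManifest()].
#' @param path file path.
#' @return `path` invisibly; `readManifest` returns the manifest.
#' @rdname manifestIO
#' @export
writeManifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "GroundTruthManifest"))
  hdr <- sprintf("# %s: %.17g",
                 c("frameIntervalS", "pixelSizeUm", "backgroundIntensity",
                   "noiseSd", "minSeparationPx"),
                 c(manifest$frameIntervalS, manifest$pixelSizeUm,
                   manifest$backgroundIntensity, manifest$noiseSd,
                   manifest$minSeparationPx))
  con <- textConnection("csvtxt", "w", local = TRUE)
  s <- manifest$scripts
  num <- vapply(s, is.numeric, logical(1))
  s[num] <- lapply(s[num], .format_full)
  write.csv(s, con, row.names = FALSE)
  close(con)
  writeLines(c(hdr, csvtxt), path)
  invisible(path)
}

#' @rdname manifestIO
#' @export
readManifest <- function(path) {
  if (!file.exists(path)) stop("cannot read manifest: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  kv <- list()
  for (h in hdr) {
    h <- sub("^#\\s*", "", h)
    kv[[trimws(sub(":.*$", "", h))]] <- as.numeric(sub("^[^:]*:", "", h))
  }
  s <- read.csv(textConnection(body), stringsAsFactors = FALSE)
  tmpl <- do.call(sporeScripts, list(spore_id = 1L, centroid_y = 0,
                                     centroid_x = 0, fate = "dormant"))
  for (cn in names(s)) {
    if (cn %in% names(tmpl) && is.numeric(tmpl[[cn]]))
      s[[cn]] <- as.numeric(s[[cn]])
  }
  s$spore_id <- as.integer(s$spore_id)
  groundTruthManifest(s,
    frameIntervalS = kv$frameIntervalS, pixelSizeUm = kv$pixelSizeUm,
    backgroundIntensity = kv$backgroundIntensity, noiseSd = kv$noiseSd,
    minSeparationPx = kv$minSeparationPx)
}
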