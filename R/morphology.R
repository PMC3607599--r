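# Thin R wrappers over the compiled binary-image primitives plus the small
# numeric helpers shared by detection and tracking.

#' Label connected components of a binary mask
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8 (default).
#' @return integer matrix; 0 = background, components numbered 1..k in
#'   column-major scan order of their first pixel.
#' @export
labelComponents <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask))
  storage.mode(mask) <- "logical"
  .label_cc(mask, as.integer(connectivity))
}

#' Binary erosion / dilation (3x3 square element, iterated)
#'
#' @param mask logical matrix.
#' @param k number of iterations (erosion/dilation radius in Chebyshev px).
#' @return logical matrix.
#' @rdname morphology
#' @export
binaryErode <- function(mask, k = 1) {
  stopifnot(is.matrix(mask))
  storage.mode(mask) <- "logical"
  .erode_bin(mask, as.integer(k))
}

#' @rdname morphology
#' @export
binaryDilate <- function(mask, k = 1) {
  stopifnot(is.matrix(mask))
  storage.mode(mask) <- "logical"
  .dilate_bin(mask, as.integer(k))
}

#' Otsu's threshold of a grayscale image
#'
#' Maximizes between-class variance over a 256-bin histogram; used as the
#' automatic phase-bright threshold when none is configured.
#'
#' @param img numeric matrix or vector of intensities.
#' @param nbins histogram bins (default 256).
#' @return the threshold intensity (bin upper edge).
#' @export
otsuThreshold <- function(img, nbins = 256) {
  v <- as.numeric(img)
  v <- v[is.finite(v)]
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = nbins + 1)
  h <- tabulate(findInterval(v, br, rightmost.closed = TRUE), nbins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  between <- rep(-Inf, nbins)
  between[valid] <- (mu_t * w0[valid] - mu[valid])^2 / (w0[valid] * w1[valid])
  # the maximum can be a plateau (e.g. well-separated modes); take its middle
  top <- which(between >= max(between) - 1e-12 * abs(max(between)))
  br[round(mean(range(top))) + 1]
}

# linear pixel indices of a filled disk centered at (cy, cx) [0-based],
# clipped to an ny x nx image; returns integer vector (1-based, column-major)
.disk_indices <- function(cy, cx, r, ny, nx) {
  y0 <- max(0, floor(cy - r)); y1 <- min(ny - 1, ceiling(cy + r))
  x0 <- max(0, floor(cx - r)); x1 <- min(nx - 1, ceiling(cx + r))
  if (y0 > y1 || x0 > x1) return(integer(0))
  ys <- y0:y1; xs <- x0:x1
  g <- expand.grid(y = ys, x = xs)
  keep <- (g$y - cy)^2 + (g$x - cx)^2 <= r^2
  as.integer(g$y[keep] + 1 + g$x[keep] * ny)
}
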