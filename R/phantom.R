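#' Procedural brain-like phantom
#'
#' Builds a piecewise-constant, brain-like emission phantom with three
#' tissue classes: an outer convoluted gray-matter band, inner white
#' matter, and zero-activity CSF (ventricles and everything outside the
#' head). The default activity levels follow the 4:1:0
#' gray:white:CSF ratio of FDG brain imaging. The head is an ellipse; the
#' gray/white boundary is modulated by two sinusoids whose phases are
#' derived deterministically from \code{seed}, producing thin
#' high-contrast cortical folds; two rotated elliptical ventricles are
#' carved out near the center. The construction is pure: identical
#' arguments give bit-identical images.
#'
#' @param size image edge length in pixels (>= 32 so the folds and
#'   ventricles stay resolvable).
#' @param levels activity levels for gray matter, white matter, CSF
#'   (nonnegative, in that order).
#' @param seed integer controlling the fold phases (no RNG state used).
#' @return Activity-image matrix whose distinct values are exactly the
#'   (distinct) entries of \code{levels}.
#' @examples
#' ph <- makeBrainPhantom(64)
#' sort(unique(as.vector(ph)))
#' @export
makeBrainPhantom <- function(size = 128L, levels = c(gray = 4, white = 1, csf = 0),
                             seed = 1L) {
  if (size < 32) stop("size must be >= 32: phantom structures unresolvable")
  if (length(levels) != 3L || any(levels < 0))
    stop("levels must be three nonnegative activities (gray, white, csf)")
  n <- as.integer(size)
  ph1 <- .seedPhase(seed, 1L)
  ph2 <- .seedPhase(seed, 2L)

  cc <- matrix(rep(seq_len(n), each = n), n, n)
  rr <- matrix(rep(seq_len(n), times = n), n, n)
  x <- (cc - (n + 1) / 2) / (0.46 * n)
  y <- ((n + 1) / 2 - rr) / (0.39 * n)
  rho <- sqrt(x^2 + y^2)
  th <- atan2(y, x)

  # gray/white boundary radius, sinusoidally convoluted
  rgw <- 0.72 + 0.10 * sin(6 * th + ph1) + 0.05 * sin(3 * th - ph2)
  rgw <- pmin(pmax(rgw, 0.45), 0.92)

  img <- matrix(levels[3L], n, n)
  img[rho <= 1] <- levels[1L]                 # gray fills the head...
  img[rho < rgw] <- levels[2L]                # ...white inside the band

  # two rotated elliptical ventricles (CSF)
  for (s in c(-1, 1)) {
    ang <- s * pi / 9
    xs <- (x - s * 0.20) * cos(ang) + (y - 0.08) * sin(ang)
    ys <- -(x - s * 0.20) * sin(ang) + (y - 0.08) * cos(ang)
    img[(xs / 0.10)^2 + (ys / 0.28)^2 <= 1] <- levels[3L]
  }
  img
}

#' Two-region disc phantom
#'
#' A centered disc of one activity level on a uniform field of another --
#' the minimal edge/flat fixture used to probe the fine-tuning mechanism.
#'
#' @param size image edge length (>= 16).
#' @param innerLevel activity inside the disc (radius size/4).
#' @param outerLevel activity outside the disc.
#' @return Activity-image matrix.
#' @export
makeTwoRegionPhantom <- function(size, innerLevel, outerLevel) {
  if (size < 16) stop("size must be >= 16")
  if (innerLevel < 0 || outerLevel < 0) stop("levels must be nonnegative")
  n <- as.integer(size)
  cc <- matrix(rep(seq_len(n), each = n), n, n)
  rr <- matrix(rep(seq_len(n), times = n), n, n)
  d2 <- (cc - (n + 1) / 2)^2 + (rr - (n + 1) / 2)^2
  img <- matrix(outerLevel, n, n)
  img[d2 <= (n / 4)^2] <- innerLevel
  img
}

#' Circular pixel mask
#'
#' Logical mask of pixels whose centers fall within \code{radius} of
#' \code{center} = (row, col).
#'
#' @param size grid edge length.
#' @param center numeric (row, col) center.
#' @param radius radius in pixels.
#' @return Logical matrix.
#' @export
discMask <- function(size, center, radius) {
  n <- as.integer(size)
  cc <- matrix(rep(seq_len(n), each = n), n, n)
  rr <- matrix(rep(seq_len(n), times = n), n, n)
  (rr - center[1L])^2 + (cc - center[2L])^2 <= radius^2
}

#' Rectangular pixel mask
#'
#' @param size grid edge length.
#' @param rows integer range c(first, last) of rows.
#' @param cols integer range c(first, last) of columns.
#' @return Logical matrix.
#' @export
rectMask <- function(size, rows, cols) {
  n <- as.integer(size)
  if (rows[1L] < 1 || rows[2L] > n || cols[1L] < 1 || cols[2L] > n)
    stop("rectangle must lie inside the grid")
  m <- matrix(FALSE, n, n)
  m[rows[1L]:rows[2L], cols[1L]:cols[2L]] <- TRUE
  m
}

# Default ROI layout scaled to the grid: five rectangular regional ROIs
# over the cortical band and deep structures, three contrast-recovery
# discs in the gray band, and a background disc in lower white matter.
#' @noRd
.defaultRoiLayout <- function(n) {
  f <- function(p) as.integer(round(p * n))
  list(
    regional = list(
      R1 = list(rows = c(f(0.18), f(0.32)), cols = c(f(0.30), f(0.46))),
      R2 = list(rows = c(f(0.18), f(0.32)), cols = c(f(0.54), f(0.70))),
      R3 = list(rows = c(f(0.44), f(0.58)), cols = c(f(0.14), f(0.30))),
      R4 = list(rows = c(f(0.44), f(0.58)), cols = c(f(0.70), f(0.86))),
      R5 = list(rows = c(f(0.66), f(0.80)), cols = c(f(0.40), f(0.60)))
    ),
    crc = list(
      C1 = list(center = c(f(0.16), f(0.50)), radius = 0.045 * n),
      C2 = list(center = c(f(0.62), f(0.135)), radius = 0.045 * n),
      C3 = list(center = c(f(0.62), f(0.865)), radius = 0.045 * n)
    ),
    background = list(center = c(f(0.66), f(0.50)), radius = 0.08 * n)
  )
}

#' Build an ROI set for quantitative evaluation
#'
#' Converts a layout of geometric primitives into boolean masks and records
#' the true contrast \eqn{CR^0_R = (\bar A_R - \bar A_{Bg}) / \bar A_{Bg}}
#' of each contrast-recovery ROI computed from the supplied reference
#' image, so that the contrast recovery coefficient of the truth itself is
#' exactly 1. The default layout scales with the grid: five rectangular
#' regional ROIs, three contrast-recovery discs over the cortical band and
#' a background disc in white matter.
#'
#' @param image reference activity image (the phantom).
#' @param layout optional list with entries \code{regional} (named list of
#'   \code{list(rows=, cols=)} rectangles), \code{crc} (named list of
#'   \code{list(center=, radius=)} discs) and \code{background}
#'   (\code{list(center=, radius=)}).
#' @return An \linkS4class{ROISet}.
#' @export
makeRois <- function(image, layout = NULL) {
  .checkImage(image, "reference image")
  n <- nrow(image)
  if (is.null(layout)) layout <- .defaultRoiLayout(n)
  regional <- lapply(layout$regional, function(p)
    rectMask(n, p$rows, p$cols))
  crc <- lapply(layout$crc, function(p) discMask(n, p$center, p$radius))
  bg <- discMask(n, layout$background$center, layout$background$radius)
  for (m in crc)
    if (any(m & bg))
      stop("contrast-recovery ROI overlaps the background region")
  bgMean <- mean(image[bg])
  if (bgMean == 0) stop("background region has zero mean activity")
  tc <- vapply(crc, function(m) (mean(image[m]) - bgMean) / bgMean,
               numeric(1))
  new("ROISet", regional = regional, crc = crc, background = bg,
      trueContrast = tc, imageSize = as.integer(n))
}

#' Rescale an activity image to a target expected count total
#'
#' Linearly rescales \code{image} so that its noiseless forward projection
#' sums exactly to \code{target}.
#'
#' @param image activity image.
#' @param model a \linkS4class{SystemModel}.
#' @param target desired total expected counts (> 0).
#' @return The rescaled image.
#' @export
scaleToCounts <- function(image, model, target) {
  .checkImage(image)
  stopifnot(target > 0)
  tot <- sum(forwardProject(model, image))
  if (tot <= 0) stop("image projects to zero total counts")
  image * (target / tot)
}
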