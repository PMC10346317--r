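# Patch-similarity machinery: squared patch differences over the four
# directed neighbor pairs, similarity weights, pixel roughness measures,
# the Butterworth modulation alpha, and the per-pair fine-tuning of the
# edge-sensitivity control parameter.

# Squared patch-difference field for all four directed neighbor offsets.
# Returns an n x n x 4 array; NA where the neighbor pixel leaves the grid.
# Patches use replicate padding so they are defined at image borders.
#' @noRd
.patchDiffField <- function(image, patchRadius = 1L) {
  r <- as.integer(patchRadius)
  n1 <- nrow(image); n2 <- ncol(image)
  pad <- r + 1L
  ip <- .padReplicate(image, pad)
  out <- array(NA_real_, c(n1, n2, 4L))
  for (k in 1:4) {
    dr <- .NB_OFFSETS[k, 1L]; dc <- .NB_OFFSETS[k, 2L]
    d <- ip[seq_len(n1 + 2L * r) + (pad - r) + dr,
            seq_len(n2 + 2L * r) + (pad - r) + dc, drop = FALSE] -
         ip[seq_len(n1 + 2L * r) + (pad - r),
            seq_len(n2 + 2L * r) + (pad - r), drop = FALSE]
    s <- .boxSumValid(d^2, r, n1, n2)
    # pairs whose neighbor is outside the grid do not exist
    if (dr == -1L) s[1L, ] <- NA
    if (dr ==  1L) s[n1, ] <- NA
    if (dc == -1L) s[, 1L] <- NA
    if (dc ==  1L) s[, n2] <- NA
    out[, , k] <- s
  }
  out
}

#' Squared patch difference between two pixels
#'
#' \eqn{\Delta\rho_{jj'} = \sum_{p=1}^{P} (f_j(p) - f_{j'}(p))^2} over the
#' \eqn{P = (2r+1)^2} aligned positions of the patches centered at pixels
#' j and j' (replicate padding at image borders). Symmetric in its two
#' pixels and zero for identical patches.
#'
#' @param image activity image.
#' @param center integer (row, col) of the first pixel.
#' @param neighbor integer (row, col) of the second pixel.
#' @param patchRadius patch radius in pixels (default 1, a 3 x 3 patch).
#' @return Nonnegative scalar.
#' @export
patchDifference <- function(image, center, neighbor, patchRadius = 1L) {
  n1 <- nrow(image); n2 <- ncol(image)
  if (any(center < 1L) || center[1L] > n1 || center[2L] > n2 ||
      any(neighbor < 1L) || neighbor[1L] > n1 || neighbor[2L] > n2)
    stop("pixels must lie inside the grid")
  r <- as.integer(patchRadius)
  ip <- .padReplicate(image, r)
  win <- function(px) ip[(px[1L]):(px[1L] + 2L * r),
                         (px[2L]):(px[2L] + 2L * r), drop = FALSE]
  sum((win(center) - win(neighbor))^2)
}

#' Patch-similarity weights
#'
#' Computes \eqn{W_{jj'} = \exp(-\Delta\rho_{jj'} / h^2)} for every
#' directed 4-neighbor pair, plus the global mean pair weight w used by
#' the fine-tuning rule. When \code{h} is NULL the bandwidth defaults to
#' the scale-free choice \eqn{h^2 = } mean of \eqn{\Delta\rho} over all
#' pairs of the image itself (floored at a machine-epsilon-scaled value so
#' constant images remain well defined); this keeps the weights spread in
#' (0, 1) whatever the intensity scale of the current estimate.
#'
#' @param image activity image (typically the estimate from the previous
#'   iteration).
#' @param h similarity bandwidth (> 0), or NULL for the data-driven
#'   default.
#' @param patchRadius patch radius in pixels (default 1: 3 x 3 patches,
#'   P = 9).
#' @param includeSelf should the self-weights \eqn{W_{jj} = 1} enter the
#'   global mean w? Default FALSE: w averages the directed neighbor pairs
#'   only.
#' @return A \linkS4class{SimilarityField}.
#' @examples
#' f <- makeTwoRegionPhantom(32, 4, 1)
#' sf <- patchSimilarity(f)
#' meanSimilarity(sf)
#' @export
patchSimilarity <- function(image, h = NULL, patchRadius = 1L,
                            includeSelf = FALSE) {
  if (!is.null(h) && h <= 0) stop("bandwidth h must be positive")
  dp <- .patchDiffField(image, patchRadius)
  if (is.null(h)) {
    h2 <- mean(dp, na.rm = TRUE)
    floorv <- .Machine$double.eps * max(1, max(abs(image))^2)
    h2 <- max(h2, floorv)
    h <- sqrt(h2)
  } else {
    h2 <- h^2
  }
  W <- exp(-dp / h2)
  w <- if (includeSelf) {
    npix <- length(image)
    (sum(W, na.rm = TRUE) + npix) / (sum(!is.na(W)) + npix)
  } else mean(W, na.rm = TRUE)
  new("SimilarityField", W = W, w = w, h = h,
      patchRadius = as.integer(patchRadius))
}

#' Gradient-magnitude roughness
#'
#' Per-pixel magnitude of the central-difference gradient (replicate
#' padding at borders, so border gradients reduce to one-sided
#' differences at half weight).
#'
#' @param image activity image.
#' @return A \linkS4class{RoughnessField} with measure "GR".
#' @export
roughnessGradient <- function(image) {
  gx <- (.shiftImage(image, 0L, 1L, "replicate") -
         .shiftImage(image, 0L, -1L, "replicate")) / 2
  gy <- (.shiftImage(image, 1L, 0L, "replicate") -
         .shiftImage(image, -1L, 0L, "replicate")) / 2
  new("RoughnessField", z = sqrt(gx^2 + gy^2), measure = "GR")
}

#' Local standard-deviation roughness
#'
#' Sample standard deviation (divisor L - 1) of the L = (2r+1)^2 values in
#' the window centered at each pixel, replicate padding at borders.
#'
#' @param image activity image.
#' @param patchRadius window radius (default 1: 3 x 3 window, L = 9).
#' @return A \linkS4class{RoughnessField} with measure "SD".
#' @export
roughnessSD <- function(image, patchRadius = 1L) {
  r <- as.integer(patchRadius)
  L <- (2 * r + 1)^2
  ip <- .padReplicate(image, r)
  s1 <- .boxSumValid(ip, r, nrow(image), ncol(image))
  s2 <- .boxSumValid(ip^2, r, nrow(image), ncol(image))
  v <- pmax(s2 - s1^2 / L, 0) / (L - 1)
  new("RoughnessField", z = sqrt(v), measure = "SD")
}

#' Mean-patch-similarity flatness
#'
#' Per-pixel mean of the similarity weights over the available directed
#' neighbors; values in (0, 1\], with high values in flat regions. The
#' formula is normalized by the neighbor count so border pixels (with
#' fewer neighbors) remain commensurate with interior pixels.
#'
#' @param field a \linkS4class{SimilarityField}.
#' @return A \linkS4class{RoughnessField} with measure "PS" (note the PS
#'   score increases with flatness, not roughness; the Butterworth
#'   modulation accounts for the orientation).
#' @export
roughnessPS <- function(field) {
  stopifnot(is(field, "SimilarityField"))
  W <- field@W
  z <- apply(W, c(1L, 2L), mean, na.rm = TRUE)
  new("RoughnessField", z = z, measure = "PS")
}

#' Butterworth modulation of a roughness field
#'
#' Maps a pixel-roughness score z smoothly into \eqn{\alpha \in [-1, 1]}
#' via the modified Butterworth polynomial
#' \eqn{\alpha = 2 / (1 + \mathrm{arg}^{2r}) - 1} with turning point t =
#' mean(z) and order \eqn{r = 0.1\lambda}. The argument is oriented per
#' measure so that flat pixels always map toward +1 and rough pixels
#' toward -1: for the rough-increasing measures GR and SD the argument is
#' \eqn{z/t}; for the flat-increasing PS measure it is \eqn{t/z}. The
#' ratio is clamped to \eqn{[10^{-12}, 10^{12}]} before powering, which
#' realizes the continuous \eqn{\pm 1} limits without overflow.
#'
#' @param roughness a \linkS4class{RoughnessField}.
#' @param lambda smoothing parameter of the reconstruction; the
#'   polynomial order is r = 0.1 * lambda.
#' @return Matrix of per-pixel \eqn{\alpha} values in \[-1, 1\].
#' @export
butterworthAlpha <- function(roughness, lambda) {
  stopifnot(is(roughness, "RoughnessField"), lambda > 0)
  z <- roughness@z
  t <- mean(z)
  if (t <= 0) stop("roughness is identically zero: turning point undefined")
  r <- 0.1 * lambda
  ratio <- if (roughness@measure == "PS") t / z else z / t
  ratio[!is.finite(ratio)] <- 1e12
  ratio <- pmin(pmax(ratio, 1e-12), 1e12)
  2 / (1 + ratio^(2 * r)) - 1
}

#' Fine-tune the control parameter from patch similarities
#'
#' The core adaptive rule: for each directed neighbor pair (j, j') the
#' control parameter becomes
#' \deqn{\delta_{jj'} = \delta_0 (1 + W_{jj'} + \alpha_j w),}
#' with \eqn{\alpha} evaluated at the pixel being updated. Around
#' irregular edges (low similarity, \eqn{\alpha \to -1}) the control drops
#' below \eqn{\delta_0}, sharpening edge preservation; in flat regions
#' (\eqn{W \approx 1}, \eqn{\alpha \to +1}) it rises toward
#' \eqn{3\delta_0}, approaching quadratic-like smoothing. Values stay in
#' \eqn{[\delta_0(1 - w), \delta_0(2 + w)]} and are strictly positive
#' whenever w < 1.
#'
#' @param delta0 initial global control value (> 0).
#' @param field a \linkS4class{SimilarityField}.
#' @param alpha per-pixel modulation matrix in \[-1, 1\] (from
#'   \code{\link{butterworthAlpha}}).
#' @return A \linkS4class{ControlField}.
#' @export
fineTuneControl <- function(delta0, field, alpha) {
  stopifnot(is(field, "SimilarityField"), delta0 > 0)
  d <- dim(field@W)
  if (!is.matrix(alpha) || any(dim(alpha) != d[1:2]))
    stop("alpha does not match the similarity grid")
  delta <- array(NA_real_, d)
  for (k in 1:4)
    delta[, , k] <- delta0 * (1 + field@W[, , k] + alpha * field@w)
  new("ControlField", delta = delta, delta0 = delta0, alpha = alpha,
      w = field@w)
}
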