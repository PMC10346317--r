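# Image-quality metrics: PSNR, SSIM, VIF (pixel domain), MAE, RMSE over
# unit-peak-normalized pairs; ensemble MPE; ROI contrast recovery.
#
# Convention: all paired metrics normalize both images by the maximum of
# the reference, so the dynamic range is 1 and PSNR = -20 log10(RMSE)
# exactly. MPE operates on the raw (unnormalized) images as its own
# normalization (by the reference energy) is built in.

#' Normalize an image pair by the reference peak
#'
#' Divides both images by max(ref), so the reference maximum becomes
#' exactly 1 (dynamic range 1 for all subsequent metrics).
#'
#' @param ref reference image with positive maximum.
#' @param test test image on the same grid.
#' @return List with elements \code{ref} and \code{test}.
#' @export
normalizePair <- function(ref, test) {
  if (!all(dim(ref) == dim(test))) stop("images must share a grid")
  m <- max(ref)
  if (m <= 0) stop("reference image must have a positive maximum")
  list(ref = ref / m, test = test / m)
}

#' Root-mean-square error
#' @param ref,test images on a common grid (normalize first for the
#'   unit-peak convention).
#' @return Nonnegative scalar.
#' @export
rmse <- function(ref, test) sqrt(mean((ref - test)^2))

#' Mean absolute error
#' @inheritParams rmse
#' @return Nonnegative scalar.
#' @export
mae <- function(ref, test) mean(abs(ref - test))

#' Peak signal-to-noise ratio (dB)
#'
#' Under unit-peak normalization, PSNR = 20 log10(1 / RMSE). Identical
#' images (RMSE = 0) return the documented cap of 200 dB rather than
#' infinity.
#'
#' @param ref,test a unit-peak-normalized pair (see
#'   \code{\link{normalizePair}}).
#' @param cap sentinel for identical images (default 200 dB).
#' @return PSNR in dB.
#' @export
psnr <- function(ref, test, cap = 200) {
  e <- rmse(ref, test)
  if (e <= 10^(-cap / 20)) return(cap)
  -20 * log10(e)
}

# 1-D Gaussian kernel of length 2r+1, sd s, normalized to sum 1
#' @noRd
.gaussKernel <- function(r, s) {
  x <- (-r):r
  k <- exp(-x^2 / (2 * s^2))
  k / sum(k)
}

# Valid-mode separable 2-D convolution with a symmetric 1-D kernel:
# output dims shrink by (length(k) - 1) per side pair.
#' @noRd
.convValid <- function(m, k) {
  r <- (length(k) - 1L) %/% 2L
  band <- function(n) {
    nb <- n - 2L * r
    B <- matrix(0, nb, n)
    for (j in seq_along(k)) B[cbind(seq_len(nb), seq_len(nb) + j - 1L)] <- k[j]
    B
  }
  out <- band(nrow(m)) %*% m
  t(band(ncol(m)) %*% t(out))
}

#' Structural similarity index (SSIM)
#'
#' Mean local SSIM with an 11 x 11 Gaussian window (sd 1.5), stability
#' constants K1 = 0.01 and K2 = 0.03, dynamic range 1 (apply to a
#' unit-peak-normalized pair). Local statistics use valid-mode windows, so
#' images must be at least 11 pixels on a side.
#'
#' @inheritParams psnr
#' @param winRadius window radius (default 5: 11 x 11).
#' @param winSigma Gaussian window sd (default 1.5).
#' @param K1,K2 stability constants.
#' @param L dynamic range (1 under unit-peak normalization).
#' @return Mean SSIM in \[-1, 1\].
#' @export
ssim <- function(ref, test, winRadius = 5L, winSigma = 1.5,
                 K1 = 0.01, K2 = 0.03, L = 1) {
  if (!all(dim(ref) == dim(test))) stop("images must share a grid")
  if (min(dim(ref)) < 2L * winRadius + 1L)
    stop("image smaller than the SSIM window")
  k <- .gaussKernel(winRadius, winSigma)
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  mu1 <- .convValid(ref, k); mu2 <- .convValid(test, k)
  s11 <- .convValid(ref * ref, k) - mu1^2
  s22 <- .convValid(test * test, k) - mu2^2
  s12 <- .convValid(ref * test, k) - mu1 * mu2
  num <- (2 * mu1 * mu2 + C1) * (2 * s12 + C2)
  den <- (mu1^2 + mu2^2 + C1) * (s11 + s22 + C2)
  mean(num / den)
}

#' Visual information fidelity (pixel domain)
#'
#' Pixel-domain VIF over four Gaussian scales. At scale s = 1..4 the
#' window has length 2^(5-s) + 1 with sd length/5; from scale 2 on, both
#' images are smoothed and decimated by 2 before computing local
#' statistics. Per scale, the local signal gain g = cov/(var_ref) and
#' residual variance feed the information ratio with additive noise
#' variance \code{sigmaNsq} (default 2); scales whose decimated image is
#' smaller than the window are skipped. Equals 1 for identical images and
#' is nonnegative.
#'
#' @inheritParams psnr
#' @param sigmaNsq visual noise variance (default 2.0).
#' @return VIF score >= 0.
#' @export
vif <- function(ref, test, sigmaNsq = 2) {
  if (!all(dim(ref) == dim(test))) stop("images must share a grid")
  eps <- 1e-10
  num <- 0; den <- 0
  r1 <- ref; t1 <- test
  for (scale in 1:4) {
    N <- 2^(4 - scale + 1) + 1
    s <- N / 5
    k <- .gaussKernel((N - 1L) %/% 2L, s)
    if (scale > 1) {
      if (min(dim(r1)) < N) break
      r1 <- .convValid(r1, k)[seq(1, nrow(r1) - N + 1, by = 2),
                              seq(1, ncol(r1) - N + 1, by = 2), drop = FALSE]
      t1 <- .convValid(t1, k)[seq(1, nrow(t1) - N + 1, by = 2),
                              seq(1, ncol(t1) - N + 1, by = 2), drop = FALSE]
    }
    if (min(dim(r1)) < N) break
    mu1 <- .convValid(r1, k); mu2 <- .convValid(t1, k)
    s11 <- pmax(.convValid(r1 * r1, k) - mu1^2, 0)
    s22 <- pmax(.convValid(t1 * t1, k) - mu2^2, 0)
    s12 <- .convValid(r1 * t1, k) - mu1 * mu2
    g <- ifelse(s11 > eps, s12 / pmax(s11, eps), 0)
    sv <- s22 - g * s12
    g <- pmax(g, 0)
    sv <- pmax(ifelse(s11 > eps, sv, s22), 0)
    num <- num + sum(log10(1 + g^2 * s11 / (sv + sigmaNsq)))
    den <- den + sum(log10(1 + s11 / sigmaNsq))
  }
  if (den == 0) return(1)
  num / den
}

#' Mean percentage error over noise trials
#'
#' \deqn{MPE = \frac{1}{K} \sum_{k=1}^{K}
#'   \sqrt{\sum_j (\hat f_j^k - f_j)^2 / \sum_j f_j^2} \times 100,}
#' computed on the raw (unnormalized) images; optionally restricted to a
#' pixel mask.
#'
#' @param ref reference image (nonzero).
#' @param trials a single reconstruction or a list of them (K trials).
#' @param mask optional logical mask restricting the sums.
#' @return Percentage (>= 0).
#' @export
mpe <- function(ref, trials, mask = NULL) {
  if (is.matrix(trials)) trials <- list(trials)
  if (!length(trials)) stop("at least one trial required")
  sel <- if (is.null(mask)) rep(TRUE, length(ref)) else as.vector(mask)
  if (!any(sel)) stop("empty mask")
  denom <- sum(ref[sel]^2)
  if (denom <= 0) stop("reference has zero energy on the mask")
  vals <- vapply(trials, function(t)
    sqrt(sum((t[sel] - ref[sel])^2) / denom), numeric(1))
  100 * mean(vals)
}

#' Contrast recovery coefficient
#'
#' \eqn{CRC_R = [(\bar A_R - \bar A_{Bg}) / \bar A_{Bg}] / CR^0_R} for
#' each contrast-recovery ROI, using the true contrasts recorded in the
#' ROI set; the reference image itself scores exactly 1 on every ROI.
#'
#' @param recon reconstructed image.
#' @param rois an \linkS4class{ROISet}.
#' @return Named numeric vector of per-ROI CRC values.
#' @export
crc <- function(recon, rois) {
  stopifnot(is(rois, "ROISet"))
  bg <- mean(recon[rois@background])
  if (bg == 0) stop("zero background mean")
  vapply(names(rois@crc), function(nm) {
    ar <- mean(recon[rois@crc[[nm]]])
    ((ar - bg) / bg) / rois@trueContrast[[nm]]
  }, numeric(1))
}

#' Mean contrast recovery coefficient over trials
#'
#' @param trials list of reconstructions (K noise trials).
#' @param rois an \linkS4class{ROISet}.
#' @return Named numeric vector: per-ROI mean CRC.
#' @export
mcrc <- function(trials, rois) {
  if (is.matrix(trials)) trials <- list(trials)
  m <- vapply(trials, crc, numeric(length(crcRois(rois))), rois = rois)
  if (is.null(dim(m))) m <- matrix(m, nrow = 1,
                                   dimnames = list(names(crcRois(rois))))
  rowMeans(m)
}

#' Regional mean percentage error
#'
#' The MPE restricted to the pixels of each rectangular regional ROI.
#'
#' @param ref reference image.
#' @param trials a single reconstruction or list of them.
#' @param rois an \linkS4class{ROISet}.
#' @return Named numeric vector of per-ROI MPE percentages.
#' @export
regionalMpe <- function(ref, trials, rois) {
  stopifnot(is(rois, "ROISet"))
  vapply(names(rois@regional), function(nm)
    mpe(ref, trials, mask = rois@regional[[nm]]), numeric(1))
}

#' All six paired image-quality metrics at once
#'
#' Normalizes the pair by the reference peak and returns PSNR, SSIM, VIF,
#' MAE, RMSE (on the normalized pair) and the single-trial MPE (raw
#' images) as a named vector.
#'
#' @param ref reference (phantom) image.
#' @param test reconstructed image.
#' @return Named numeric vector.
#' @export
iqaMetrics <- function(ref, test) {
  np <- normalizePair(ref, test)
  c(PSNR = psnr(np$ref, np$test),
    SSIM = ssim(np$ref, np$test),
    VIF = vif(np$ref, np$test),
    MAE = mae(np$ref, np$test),
    RMSE = rmse(np$ref, np$test),
    MPE = mpe(ref, test))
}
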