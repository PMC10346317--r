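#' Build a parallel-beam system model
#'
#' Constructs the sparse system matrix H of a 2-D parallel-beam geometry:
#' \code{nAngles} views uniformly spaced over \[0, 180) degrees, each with
#' \code{nBins} detector bins at unit spacing centered on the grid. The
#' weight \eqn{H_{ij}} is the exact length of intersection of the central
#' ray of bin i with pixel j (unit pixel spacing, grid centered at the
#' origin). For a line at angle \eqn{\theta} and signed offset u from a
#' pixel center, the chord length through the unit square follows the
#' closed-form trapezoid profile with half-widths
#' \eqn{p_1 = (|\cos\theta| + |\sin\theta|)/2} and
#' \eqn{p_2 = ||\cos\theta| - |\sin\theta||/2}: constant
#' \eqn{1/\max(|\cos\theta|, |\sin\theta|)} for \eqn{|u| \le p_2}, linearly
#' decaying to zero at \eqn{|u| = p_1}. Forward projection and
#' backprojection are therefore exact adjoints by construction (one shared
#' sparse matrix).
#'
#' The detector (nBins at unit spacing) must cover the image
#' (\code{nBins >= imageSize}); activity outside the inscribed circle of
#' the grid is only partially sampled at oblique views, so phantoms are
#' expected to live inside the field of view.
#'
#' @param nBins detector bins per view (>= 1).
#' @param nAngles number of views over 180 degrees (>= 1).
#' @param imageSize image edge length in pixels.
#' @return A \linkS4class{SystemModel}.
#' @examples
#' m <- buildSystemModel(32, 32, 32)
#' dim(systemMatrix(m))
#' @export
buildSystemModel <- function(nBins, nAngles, imageSize) {
  stopifnot(nBins >= 1, nAngles >= 1, imageSize >= 1)
  if (nBins < imageSize)
    stop("image larger than detector coverage (need nBins >= imageSize)")
  nBins <- as.integer(nBins); nAngles <- as.integer(nAngles)
  imageSize <- as.integer(imageSize)
  n <- imageSize
  angles <- (seq_len(nAngles) - 1L) * pi / nAngles

  # pixel centers, column-major to match as.vector(image)
  cc <- rep(seq_len(n), each = n)            # column index
  rr <- rep(seq_len(n), times = n)           # row index
  px <- cc - (n + 1) / 2
  py <- (n + 1) / 2 - rr
  tb <- seq_len(nBins) - (nBins + 1) / 2     # detector bin offsets

  ilist <- vector("list", nAngles)
  jlist <- vector("list", nAngles)
  xlist <- vector("list", nAngles)
  for (v in seq_len(nAngles)) {
    th <- angles[v]
    a <- abs(cos(th)); b <- abs(sin(th))
    p1 <- (a + b) / 2
    p2 <- abs(a - b) / 2
    hmax <- 1 / max(a, b)
    tc <- px * cos(th) + py * sin(th)        # offset of each pixel center
    # candidate bins: all with |tb - tc| < p1 (at most 2 at unit spacing
    # since 2 * p1 <= sqrt(2))
    b0 <- floor(tc - p1 + (nBins + 1) / 2 - 1) + 1   # first candidate bin
    ii <- jj <- ww <- vector("list", 3L)
    for (k in 0:2) {
      bin <- b0 + k
      ok <- bin >= 1L & bin <= nBins
      u <- abs(tb[pmin(pmax(bin, 1L), nBins)] - tc)
      len <- ifelse(u <= p2, hmax,
                    ifelse(u < p1, (p1 - u) / pmax(a * b, 1e-300), 0))
      keep <- ok & len > 0
      ii[[k + 1L]] <- (v - 1L) * nBins + bin[keep]
      jj[[k + 1L]] <- which(keep)
      ww[[k + 1L]] <- len[keep]
    }
    ilist[[v]] <- unlist(ii)
    jlist[[v]] <- unlist(jj)
    xlist[[v]] <- unlist(ww)
  }
  H <- Matrix::sparseMatrix(i = unlist(ilist), j = unlist(jlist),
                            x = unlist(xlist),
                            dims = c(nAngles * nBins, n * n))
  new("SystemModel", H = methods::as(H, "CsparseMatrix"), nBins = nBins,
      nAngles = nAngles, imageSize = imageSize, angles = angles)
}

#' Forward projection
#'
#' Computes the noiseless sinogram \eqn{(Hf)_i = \sum_j H_{ij} f_j}.
#'
#' @param model a \linkS4class{SystemModel}.
#' @param image square activity matrix matching the model grid.
#' @return Sinogram matrix (nAngles x nBins) of nonnegative reals.
#' @export
forwardProject <- function(model, image) {
  stopifnot(is(model, "SystemModel"))
  if (!is.matrix(image) || any(dim(image) != model@imageSize))
    stop("image does not match the model grid")
  v <- as.numeric(model@H %*% as.vector(image))
  t(matrix(v, nrow = model@nBins, ncol = model@nAngles))
}

#' Backprojection (adjoint of forward projection)
#'
#' Computes \eqn{(H^T y)_j = \sum_i H_{ij} y_i}.
#'
#' @param model a \linkS4class{SystemModel}.
#' @param sinogram matrix (nAngles x nBins).
#' @return Activity-image matrix.
#' @export
backProject <- function(model, sinogram) {
  stopifnot(is(model, "SystemModel"))
  if (!is.matrix(sinogram) ||
      any(dim(sinogram) != c(model@nAngles, model@nBins)))
    stop("sinogram does not match the model")
  v <- as.numeric(Matrix::crossprod(model@H, as.vector(t(sinogram))))
  matrix(v, model@imageSize, model@imageSize)
}

#' Sensitivity image
#'
#' Pixel j holds \eqn{\sum_{i \in S} H_{ij}}, the backprojection of a
#' unit sinogram restricted to the rays S (all rays by default, or one
#' subset of a partition).
#'
#' @param model a \linkS4class{SystemModel}.
#' @param partition optional \linkS4class{SubsetPartition}.
#' @param subset optional subset index into \code{partition}.
#' @return Activity-image matrix of per-pixel sensitivities.
#' @export
sensitivityImage <- function(model, partition = NULL, subset = NULL) {
  stopifnot(is(model, "SystemModel"))
  if (is.null(subset)) {
    v <- Matrix::colSums(model@H)
  } else {
    stopifnot(is(partition, "SubsetPartition"))
    rays <- partition@rays[[subset]]
    if (!length(rays)) stop("empty subset")
    v <- Matrix::colSums(model@H[rays, , drop = FALSE])
  }
  matrix(as.numeric(v), model@imageSize, model@imageSize)
}

#' Partition the rays of a model into ordered subsets
#'
#' Views are interleaved: view v is assigned to subset 1 + (v - 1) mod Q,
#' and all rays of a view share its subset.
#'
#' @param model a \linkS4class{SystemModel}.
#' @param Q number of subsets, 1 <= Q <= nAngles.
#' @return A \linkS4class{SubsetPartition}.
#' @export
makeSubsets <- function(model, Q) {
  stopifnot(is(model, "SystemModel"), Q >= 1)
  if (Q > model@nAngles) stop("Q must not exceed the number of views")
  Q <- as.integer(Q)
  views <- lapply(seq_len(Q), function(q)
    seq.int(q, model@nAngles, by = Q))
  rays <- lapply(views, function(vs)
    as.integer(outer(seq_len(model@nBins), (vs - 1L) * model@nBins, "+")))
  new("SubsetPartition", rays = rays, views = views, nSubsets = Q,
      nAngles = model@nAngles, nBins = model@nBins)
}

#' Simulate a Poisson emission scan
#'
#' Rescales the ground-truth activity so that its noiseless projection sums
#' to \code{targetCounts} (see \code{\link{scaleToCounts}}), then draws each
#' sinogram bin independently from a Poisson distribution with the
#' noiseless bin value as mean. The RNG state of the caller is left
#' untouched; the draw is reproducible from \code{seed}.
#'
#' @param model a \linkS4class{SystemModel}.
#' @param truth ground-truth activity image.
#' @param targetCounts expected total number of detected counts (> 0).
#' @param seed integer seed for the noise draw.
#' @return List with elements \code{truth} (the rescaled ground truth),
#'   \code{expected} (noiseless sinogram), and \code{sinogram} (Poisson
#'   realization, integer counts).
#' @export
simulateScan <- function(model, truth, targetCounts, seed) {
  if (targetCounts <= 0) stop("targetCounts must be positive")
  scaled <- scaleToCounts(truth, model, targetCounts)
  lam <- forwardProject(model, scaled)
  noisy <- .withSeed(seed, matrix(stats::rpois(length(lam), as.vector(lam)),
                                  nrow(lam), ncol(lam)))
  list(truth = scaled, expected = lam, sinogram = noisy)
}
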