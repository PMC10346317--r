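#' @import methods
#' @importClassesFrom Matrix dgCMatrix
NULL

#' Parallel-beam system model
#'
#' Discrete 2-D parallel-beam projection operator for emission tomography.
#' Rows of the sparse weight matrix index rays (detector bin within view,
#' views over 180 degrees); columns index image pixels in R column-major
#' order. Each weight is the exact length of intersection of the central
#' ray of a detector bin with a pixel, so forward projection and
#' backprojection form an exact adjoint pair.
#'
#' @slot H sparse nonnegative weight matrix, (nAngles * nBins) x imageSize^2;
#'   ray index i = (view - 1) * nBins + bin.
#' @slot nBins number of detector bins per view.
#' @slot nAngles number of views over \[0, 180) degrees.
#' @slot imageSize image edge length in pixels (unit pixel spacing).
#' @slot angles view angles in radians.
#' @export
setClass("SystemModel",
         representation(H = "dgCMatrix",
                        nBins = "integer",
                        nAngles = "integer",
                        imageSize = "integer",
                        angles = "numeric"),
         validity = function(object) {
           msg <- NULL
           if (nrow(object@H) != object@nBins * object@nAngles)
             msg <- c(msg, "nrow(H) must equal nBins * nAngles")
           if (ncol(object@H) != object@imageSize^2)
             msg <- c(msg, "ncol(H) must equal imageSize^2")
           if (length(object@angles) != object@nAngles)
             msg <- c(msg, "angles must have one entry per view")
           if (length(object@H@x) && min(object@H@x) < 0)
             msg <- c(msg, "system weights must be nonnegative")
           if (is.null(msg)) TRUE else msg
         })

#' Ordered-subsets partition of the rays of a system model
#'
#' Views are assigned to subsets by interleaving (view v goes to subset
#' 1 + (v - 1) mod Q), so all rays of a view share a subset and subset view
#' counts differ by at most one.
#'
#' @slot rays list of integer ray-index vectors, one per subset.
#' @slot views list of integer view-index vectors, one per subset.
#' @slot nSubsets number of subsets Q.
#' @slot nAngles,nBins geometry of the parent model.
#' @export
setClass("SubsetPartition",
         representation(rays = "list", views = "list", nSubsets = "integer",
                        nAngles = "integer", nBins = "integer"),
         validity = function(object) {
           msg <- NULL
           all_rays <- sort(unlist(object@rays))
           if (!identical(all_rays, seq_len(object@nAngles * object@nBins)))
             msg <- c(msg, "subsets must partition all rays")
           sizes <- lengths(object@views)
           if (length(sizes) && diff(range(sizes)) > 1L)
             msg <- c(msg, "subset view counts must differ by at most 1")
           if (is.null(msg)) TRUE else msg
         })

#' Edge-preserving penalty specification
#'
#' One of the quadratic (QD) penalty, the Lange (LN) penalty
#' \eqn{\delta^2(|\xi|/\delta - \log(1 + |\xi|/\delta))}, or the Huber (HB)
#' penalty (\eqn{\xi^2} below the knee \eqn{\sigma}, linear growth above).
#' The control parameter (\eqn{\delta} for LN, \eqn{\sigma} for HB) sets the
#' edge-preservation sensitivity; it is unused for QD.
#'
#' @slot kind one of "QD", "LN", "HB".
#' @slot control positive control parameter (ignored for QD).
#' @export
setClass("PenaltySpec",
         representation(kind = "character", control = "numeric"),
         validity = function(object) {
           msg <- NULL
           if (!object@kind %in% c("QD", "LN", "HB"))
             msg <- c(msg, "kind must be one of QD, LN, HB")
           if (object@kind != "QD" &&
               (length(object@control) != 1L || !is.finite(object@control) ||
                object@control <= 0))
             msg <- c(msg, "control must be a positive scalar for LN/HB")
           if (is.null(msg)) TRUE else msg
         })

#' Patch-similarity weights over directed neighbor pairs
#'
#' Non-local-means style weights \eqn{W_{jj'} = \exp(-\Delta\rho_{jj'}/h^2)}
#' for the four directed neighbor pairs of each pixel, with the squared patch
#' difference \eqn{\Delta\rho} accumulated over aligned patch positions
#' (replicate boundary padding). Entries for pairs whose neighbor falls
#' outside the grid are NA. The self-weight is identically 1 and is excluded
#' from the global mean unless requested at construction.
#'
#' @slot W numeric array n x n x 4 (slices N, S, W, E) of pair weights in
#'   (0, 1\]; NA marks a missing neighbor.
#' @slot w global mean pair weight in (0, 1\].
#' @slot h similarity bandwidth actually used (positive).
#' @slot patchRadius patch radius in pixels (patch edge 2 * radius + 1).
#' @export
setClass("SimilarityField",
         representation(W = "array", w = "numeric", h = "numeric",
                        patchRadius = "integer"),
         validity = function(object) {
           msg <- NULL
           if (length(dim(object@W)) != 3L || dim(object@W)[3L] != 4L)
             msg <- c(msg, "W must be an n x n x 4 array")
           wv <- object@W[!is.na(object@W)]
           if (length(wv) && (min(wv) <= 0 || max(wv) > 1 + 1e-12))
             msg <- c(msg, "weights must lie in (0, 1]")
           if (object@w <= 0 || object@w > 1 + 1e-12)
             msg <- c(msg, "mean weight w must lie in (0, 1]")
           if (object@h <= 0)
             msg <- c(msg, "bandwidth h must be positive")
           if (is.null(msg)) TRUE else msg
         })

#' Per-pixel roughness (or flatness) field
#'
#' @slot z nonnegative per-pixel score.
#' @slot measure one of "GR" (gradient magnitude), "SD" (local standard
#'   deviation) -- both increase with roughness -- or "PS" (mean patch
#'   similarity), which increases with flatness.
#' @export
setClass("RoughnessField",
         representation(z = "matrix", measure = "character"),
         validity = function(object) {
           msg <- NULL
           if (!object@measure %in% c("GR", "SD", "PS"))
             msg <- c(msg, "measure must be one of GR, SD, PS")
           if (anyNA(object@z) || any(object@z < 0))
             msg <- c(msg, "roughness must be nonnegative")
           if (is.null(msg)) TRUE else msg
         })

#' Fine-tuned control parameter per directed neighbor pair
#'
#' Holds \eqn{\delta_{jj'} = \delta_0 (1 + W_{jj'} + \alpha_j w)} together
#' with the ingredients it was computed from.
#'
#' @slot delta numeric array n x n x 4 of per-pair control values (NA for
#'   missing neighbors).
#' @slot delta0 initial global control value.
#' @slot alpha per-pixel Butterworth modulation in \[-1, 1\].
#' @slot w global mean similarity used in the tuning rule.
#' @export
setClass("ControlField",
         representation(delta = "array", delta0 = "numeric",
                        alpha = "matrix", w = "numeric"),
         validity = function(object) {
           msg <- NULL
           dv <- object@delta[!is.na(object@delta)]
           if (length(dv) && min(dv) < 0)
             msg <- c(msg, "control values must be nonnegative")
           if (any(object@alpha < -1 - 1e-9) || any(object@alpha > 1 + 1e-9))
             msg <- c(msg, "alpha must lie in [-1, 1]")
           if (object@delta0 <= 0)
             msg <- c(msg, "delta0 must be positive")
           if (is.null(msg)) TRUE else msg
         })

#' Region-of-interest set for quantitative evaluation
#'
#' Rectangular regional ROIs for regional percentage error, circular ROIs
#' for contrast recovery, and a circular background region. The true
#' contrast of each contrast-recovery ROI relative to the background is
#' recorded from the reference image at construction.
#'
#' @slot regional named list of logical masks (rectangles R1, R2, ...).
#' @slot crc named list of logical masks (discs).
#' @slot background logical mask (disc).
#' @slot trueContrast named true contrasts of the crc ROIs.
#' @slot imageSize grid edge length.
#' @export
setClass("ROISet",
         representation(regional = "list", crc = "list",
                        background = "matrix", trueContrast = "numeric",
                        imageSize = "integer"),
         validity = function(object) {
           msg <- NULL
           n <- object@imageSize
           okdim <- function(m) is.matrix(m) && all(dim(m) == c(n, n))
           if (!all(vapply(object@regional, okdim, logical(1))) ||
               !all(vapply(object@crc, okdim, logical(1))) ||
               !okdim(object@background))
             msg <- c(msg, "all masks must match the image grid")
           cr <- object@crc
           if (length(cr) > 1L) {
             acc <- matrix(0L, n, n)
             for (m in cr) acc <- acc + m
             if (any(acc > 1L))
               msg <- c(msg, "crc ROIs must be pairwise disjoint")
           }
           for (m in cr)
             if (any(m & object@background))
               msg <- c(msg, "crc ROIs must not overlap the background")
           if (length(object@trueContrast) != length(cr))
             msg <- c(msg, "one true contrast per crc ROI required")
           if (is.null(msg)) TRUE else msg
         })

#' Result of an iterative reconstruction run
#'
#' @slot estimate reconstructed activity image (strictly positive).
#' @slot method label such as "EM-ML", "COSEM-ML", "PL-LN", "SDPL-HB-SD".
#' @slot history per-outer-iteration objective values (penalized energy for
#'   PL/SDPL runs, Poisson log-likelihood for ML runs).
#' @slot config list of the settings the run used.
#' @slot control final \linkS4class{ControlField} for SDPL runs, else NULL.
#' @export
setClass("ReconResult",
         representation(estimate = "matrix", method = "character",
                        history = "numeric", config = "list",
                        control = "ANY"))
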