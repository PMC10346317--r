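# COSEM-ML / COSEM-PL / SDPL reconstruction with separable paraboloidal
# surrogate (SPS) pixel updates.
#
# State layout (plain list, documented here once):
#   f         current estimate, imageSize x imageSize, strictly positive
#   A         per-subset complete-data accumulators, npix x Q matrix;
#             A[j, q] = sum_{i in S_q} C_ij (the only statistic the pixel
#             update needs; the complete data C is never materialized)
#   sens      full sensitivity vector sum_i H_ij (length npix)
#   partition SubsetPartition
#   eps       positivity floor
#
# Energy convention: the pixel-update coefficients (a = 8 lambda sum psi,
# b = sens - 4 lambda sum psi (f_j + f_j')) carry an overall pair factor of
# 4 relative to a single count of each unordered neighbor pair. The energy
# reported by penalizedObjective() uses the matching weight -- data term
# plus 2 * lambda * sum over *directed* pairs of phi (equivalently 4 lambda
# per unordered pair) -- which is exactly the objective the iteration
# provably decreases; see the methods vignette.

#' Initialize a reconstruction state
#'
#' The initial estimate is uniform, scaled so its predicted total counts
#' match the measured total; the complete-data accumulators are then
#' filled by one C-update pass over every subset.
#'
#' @param g measured sinogram (nAngles x nBins, nonnegative).
#' @param model a \linkS4class{SystemModel}.
#' @param partition a \linkS4class{SubsetPartition} of the model's rays.
#' @return State list (see source for layout).
#' @export
initReconState <- function(g, model, partition) {
  stopifnot(is(model, "SystemModel"), is(partition, "SubsetPartition"))
  if (any(g < 0)) stop("sinogram must be nonnegative")
  tot <- sum(g)
  if (tot <= 0) stop("all-zero sinogram")
  sH <- sum(model@H@x)
  u <- tot / sH
  npix <- model@imageSize^2
  state <- list(f = matrix(u, model@imageSize, model@imageSize),
                A = matrix(0, npix, partition@nSubsets),
                sens = as.numeric(Matrix::colSums(model@H)),
                partition = partition,
                eps = 1e-12 * u)
  gvec <- as.vector(t(g))
  for (q in seq_len(partition@nSubsets))
    state <- cosemCUpdate(state, model, gvec, q, vectorized = TRUE)
  state
}

# g may be passed as the raw sinogram matrix or pre-vectorized (ray order)
#' Complete-data accumulator update for one subset
#'
#' The COSEM E-step restricted to subset q: with the current estimate f,
#' \deqn{A_j^{(q)} \gets f_j \sum_{i \in S_q} H_{ij}\, g_i / (Hf)_i.}
#' Accumulators of other subsets are left untouched (stale, as COSEM
#' prescribes). Implicitly the complete data satisfies
#' \eqn{\sum_j C_{ij} = g_i} on every visited ray. Rays with measured
#' counts but zero predicted intensity indicate a model/support
#' inconsistency and are flagged with a warning (their ratio is dropped).
#'
#' @param state state list from \code{\link{initReconState}}.
#' @param model a \linkS4class{SystemModel}.
#' @param g measured sinogram (matrix), or its ray-ordered vector.
#' @param q subset index.
#' @param vectorized set TRUE when g is already the ray-ordered vector.
#' @return The updated state.
#' @export
cosemCUpdate <- function(state, model, g, q, vectorized = FALSE) {
  gvec <- if (vectorized) g else as.vector(t(g))
  rays <- state$partition@rays[[q]]
  Hq <- model@H[rays, , drop = FALSE]
  fvec <- as.vector(state$f)
  proj <- as.numeric(Hq %*% fvec)
  gq <- gvec[rays]
  bad <- proj <= 0 & gq > 0
  if (any(bad))
    warning("measured counts on ", sum(bad),
            " ray(s) with zero predicted intensity")
  ratio <- ifelse(proj > 0, gq / proj, 0)
  state$A[, q] <- fvec * as.numeric(Matrix::crossprod(Hq, ratio))
  state
}

#' Positive root of the SPS pixel quadratic
#'
#' Solves \eqn{a f^2 + b f + c = 0} for the nonnegative root
#' \eqn{f = (-b + \sqrt{b^2 - 4ac}) / (2a)} (with the linear fallback
#' \eqn{f = -c/b} when a = 0), vectorized over pixels, using the
#' numerically stable branch \eqn{-2c / (b + \sqrt{b^2 - 4ac})} when
#' b > 0. Requires \eqn{a \ge 0} and \eqn{c \le 0}, which make the root
#' real and nonnegative; the result is clamped to the positivity floor.
#'
#' @param a quadratic coefficients (>= 0).
#' @param b linear coefficients.
#' @param c constant coefficients (<= 0).
#' @param floor positivity floor (default 0).
#' @return Nonnegative roots, same shape as the inputs.
#' @export
solvePixelQuadratic <- function(a, b, c, floor = 0) {
  len <- max(length(a), length(b), length(c))
  a <- rep_len(a, len); b <- rep_len(b, len); c <- rep_len(c, len)
  if (any(a < 0)) stop("quadratic coefficient a must be >= 0")
  if (any(c > 0)) stop("constant coefficient c must be <= 0")
  if (any(a == 0 & b <= 0 & c < 0))
    stop("no nonnegative root: a = 0 with b <= 0 and c < 0")
  disc <- sqrt(pmax(b^2 - 4 * a * c, 0))
  out <- ifelse(a > 0,
                ifelse(b > 0, -2 * c / (b + disc), (disc - b) / (2 * a)),
                ifelse(b > 0, -c / b, 0))
  pmax(out, floor)
}

#' SPS pixel update for one subset iteration
#'
#' Updates every pixel by minimizing its separable paraboloidal surrogate:
#' with \eqn{\psi} evaluated at the pre-update differences
#' \eqn{\xi_{jj'} = f_j - f_{j'}} (per-pair control values when a
#' \linkS4class{ControlField} is supplied),
#' \deqn{a_j = 8\lambda \sum_{j'} \psi,\quad
#'       b_j = \sum_i H_{ij} - 4\lambda \sum_{j'} \psi (f_j + f_{j'}),
#'       \quad c_j = -\sum_q A_j^{(q)},}
#' and \eqn{f_j} becomes the positive root of the quadratic. All pixels
#' are updated from the pre-update estimate (Jacobi sweep). With
#' \eqn{\lambda = 0} this reduces exactly to the COSEM-ML M-step
#' \eqn{f_j = \sum_q A_j^{(q)} / \sum_i H_{ij}}.
#'
#' @param state state list.
#' @param penalty a \linkS4class{PenaltySpec}.
#' @param lambda smoothing parameter (>= 0).
#' @param control NULL (use the penalty's global control) or a
#'   \linkS4class{ControlField} of per-pair values.
#' @return The updated state.
#' @export
cosemFUpdate <- function(state, penalty, lambda, control = NULL) {
  f <- state$f
  Atot <- rowSums(state$A)
  if (lambda > 0) {
    aPen <- 0; bPen <- 0
    for (k in 1:4) {
      nb <- .shiftImage(f, .NB_OFFSETS[k, 1L], .NB_OFFSETS[k, 2L], "na")
      xi <- f - nb
      ctl <- if (is.null(control)) NULL else control@delta[, , k]
      ps <- penaltyCurvature(penalty, xi, control = ctl)
      miss <- is.na(ps)
      ps[miss] <- 0
      nb[is.na(nb)] <- 0
      aPen <- aPen + ps
      bPen <- bPen + ps * (f + nb)
    }
    a <- 8 * lambda * aPen
    b <- state$sens - 4 * lambda * as.vector(bPen)
    a <- as.vector(a)
  } else {
    a <- 0
    b <- state$sens
  }
  froot <- solvePixelQuadratic(a, b, -Atot, floor = state$eps)
  state$f <- matrix(froot, nrow(f), ncol(f))
  state
}

#' Classic EM-ML reconstruction
#'
#' Maximum-likelihood expectation maximization:
#' \deqn{f_j \gets \frac{f_j}{\sum_i H_{ij}} \sum_i H_{ij}
#'       \frac{g_i}{(Hf)_i}.}
#' Initialization is uniform with matched total predicted counts. The
#' recorded history is the Poisson log-likelihood (up to a constant),
#' which EM never decreases.
#'
#' @param g measured sinogram.
#' @param model a \linkS4class{SystemModel}.
#' @param iterations number of iterations (>= 1).
#' @param keepHistory record the log-likelihood per iteration.
#' @return A \linkS4class{ReconResult} with method "EM-ML".
#' @export
runEMML <- function(g, model, iterations, keepHistory = TRUE) {
  stopifnot(iterations >= 1)
  if (any(g < 0)) stop("sinogram must be nonnegative")
  tot <- sum(g)
  if (tot <= 0) stop("all-zero sinogram")
  gvec <- as.vector(t(g))
  u <- tot / sum(model@H@x)
  fvec <- rep(u, model@imageSize^2)
  sens <- as.numeric(Matrix::colSums(model@H))
  eps <- 1e-12 * u
  hist <- numeric(0)
  for (it in seq_len(iterations)) {
    proj <- as.numeric(model@H %*% fvec)
    ratio <- ifelse(proj > 0, gvec / proj, 0)
    fvec <- pmax(fvec / pmax(sens, .Machine$double.xmin) *
                   as.numeric(Matrix::crossprod(model@H, ratio)), eps)
    if (keepHistory) {
      proj <- as.numeric(model@H %*% fvec)
      ll <- sum(ifelse(gvec > 0, gvec * log(pmax(proj, .Machine$double.xmin)),
                       0)) - sum(proj)
      hist <- c(hist, ll)
    }
  }
  new("ReconResult",
      estimate = matrix(fvec, model@imageSize, model@imageSize),
      method = "EM-ML", history = hist,
      config = list(iterations = iterations))
}

#' Penalized-likelihood energy
#'
#' Evaluates the energy the COSEM-PL/SDPL iteration decreases:
#' \deqn{E(f) = \sum_i \left[(Hf)_i - g_i \log (Hf)_i\right] +
#'       2\lambda \sum_j \sum_{j' \in N_j} \varphi(f_j - f_{j'};
#'       \delta_{jj'}).}
#' The data term is the Poisson negative log-likelihood up to a constant.
#' The factor 2 on the directed pair sum (each unordered pair accumulates
#' total weight \eqn{4\lambda}) matches the curvature convention of the
#' SPS pixel-update coefficients, so fixed-parameter runs decrease this
#' energy monotonically. Rays with measured counts but zero predicted
#' intensity make the energy infinite.
#'
#' @param f activity image (positive).
#' @param g measured sinogram.
#' @param model a \linkS4class{SystemModel}.
#' @param penalty a \linkS4class{PenaltySpec}.
#' @param lambda smoothing parameter (>= 0).
#' @param control NULL or a \linkS4class{ControlField}.
#' @return Scalar energy (possibly Inf).
#' @export
penalizedObjective <- function(f, g, model, penalty, lambda, control = NULL) {
  proj <- as.numeric(model@H %*% as.vector(f))
  gvec <- as.vector(t(g))
  if (any(proj <= 0 & gvec > 0)) return(Inf)
  pos <- gvec > 0
  datafit <- sum(proj) - sum(gvec[pos] * log(proj[pos]))
  if (lambda == 0) return(datafit)
  pen <- 0
  for (k in 1:4) {
    nb <- .shiftImage(f, .NB_OFFSETS[k, 1L], .NB_OFFSETS[k, 2L], "na")
    xi <- f - nb
    ctl <- if (is.null(control)) NULL else control@delta[, , k]
    ph <- penaltyValue(penalty, xi, control = ctl)
    pen <- pen + sum(ph, na.rm = TRUE)
  }
  datafit + 2 * lambda * pen
}

#' COSEM-ML / COSEM-PL / SDPL reconstruction
#'
#' Runs the complete-data ordered-subsets algorithm: per outer iteration,
#' each subset performs a C-update (complete-data accumulation) followed
#' by an SPS pixel update. With \code{lambda = 0} this is COSEM-ML (and
#' with \code{subsets = 1} classic EM-ML). With \code{sdpl = TRUE} the
#' similarity field, roughness measure, Butterworth modulation and
#' per-pair control field are recomputed once per outer iteration from
#' the previous outer estimate (adaptive tuning sits outside the subset
#' loop), making the control parameter spatially varying.
#'
#' @param g measured sinogram (nAngles x nBins).
#' @param model a \linkS4class{SystemModel}.
#' @param penalty a \linkS4class{PenaltySpec} ("QD", "LN", "HB" with its
#'   initial control value delta0 / sigma0).
#' @param lambda smoothing parameter (>= 0; 0 gives ML).
#' @param subsets number of ordered subsets Q (>= 1).
#' @param iterations number of outer iterations (>= 1).
#' @param sdpl enable similarity-driven per-pair control fine-tuning.
#' @param measure roughness measure for SDPL: "SD", "GR" or "PS".
#' @param h similarity bandwidth, NULL for the data-driven default.
#' @param patchRadius patch radius for the similarity field.
#' @param keepHistory record the penalized energy per outer iteration
#'   (for SDPL, evaluated at that iteration's frozen control field).
#' @return A \linkS4class{ReconResult}.
#' @examples
#' ph <- makeBrainPhantom(32)
#' m <- buildSystemModel(32, 32, 32)
#' scan <- simulateScan(m, ph, 4e4, seed = 7)
#' res <- runCosem(scan$sinogram, m, penaltySpec("LN", 0.1), lambda = 20,
#'                 subsets = 4, iterations = 5, sdpl = TRUE, measure = "SD")
#' res
#' @export
runCosem <- function(g, model, penalty = penaltySpec("QD"), lambda = 0,
                     subsets = 1L, iterations = 10L, sdpl = FALSE,
                     measure = c("SD", "GR", "PS"), h = NULL,
                     patchRadius = 1L, keepHistory = TRUE) {
  measure <- match.arg(measure)
  stopifnot(is(model, "SystemModel"), lambda >= 0, iterations >= 1)
  if (sdpl && lambda <= 0)
    stop("sdpl fine-tuning requires lambda > 0")
  if (sdpl && penalty@kind == "QD")
    stop("sdpl fine-tuning applies to the LN and HB penalties")
  partition <- makeSubsets(model, subsets)
  state <- initReconState(g, model, partition)
  gvec <- as.vector(t(g))
  hist <- numeric(0)
  ctl <- NULL
  for (n in seq_len(iterations)) {
    if (sdpl && diff(range(state$f)) > 0) {
      # a constant estimate (the uniform initialization) carries no
      # structure to tune from; such iterations use the fixed control
      sf <- patchSimilarity(state$f, h = h, patchRadius = patchRadius)
      z <- switch(measure,
                  GR = roughnessGradient(state$f),
                  SD = roughnessSD(state$f, patchRadius),
                  PS = roughnessPS(sf))
      alpha <- butterworthAlpha(z, lambda)
      ctl <- fineTuneControl(penalty@control, sf, alpha)
    }
    for (q in seq_len(partition@nSubsets)) {
      state <- cosemCUpdate(state, model, gvec, q, vectorized = TRUE)
      state <- cosemFUpdate(state, penalty, lambda, control = ctl)
    }
    if (keepHistory)
      hist <- c(hist, penalizedObjective(state$f, g, model, penalty,
                                         lambda, control = ctl))
  }
  method <- if (lambda == 0) {
    if (subsets == 1L) "EM-ML" else "COSEM-ML"
  } else if (sdpl) {
    paste0("SDPL-", penalty@kind, "-", measure)
  } else {
    paste0("PL-", penalty@kind)
  }
  new("ReconResult", estimate = state$f, method = method, history = hist,
      config = list(penalty = penalty@kind, control0 = penalty@control,
                    lambda = lambda, subsets = as.integer(subsets),
                    iterations = as.integer(iterations), sdpl = sdpl,
                    measure = if (sdpl) measure else NA_character_,
                    h = h, patchRadius = as.integer(patchRadius)),
      control = ctl)
}
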