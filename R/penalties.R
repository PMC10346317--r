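#' Construct a penalty specification
#'
#' @param kind "QD" (quadratic), "LN" (Lange), or "HB" (Huber).
#' @param control positive control parameter: \eqn{\delta} for LN,
#'   \eqn{\sigma} for HB; ignored for QD.
#' @return A \linkS4class{PenaltySpec}.
#' @examples
#' penaltyValue(penaltySpec("LN", 1), 1)   # 1 - log(2)
#' @export
penaltySpec <- function(kind = c("QD", "LN", "HB"), control = 1) {
  kind <- match.arg(kind)
  new("PenaltySpec", kind = kind, control = as.numeric(control))
}

#' @noRd
.resolveControl <- function(spec, xi, control) {
  if (is.null(control)) return(spec@control)
  if (length(control) != 1L && length(control) != length(xi))
    stop("control must be scalar or match xi in length")
  control
}

#' Penalty function value
#'
#' Evaluates the potential \eqn{\varphi(\xi)} of a penalty on intensity
#' differences \eqn{\xi}: \eqn{\xi^2} (QD);
#' \eqn{\delta^2(|\xi|/\delta - \log(1+|\xi|/\delta))} (LN);
#' \eqn{\xi^2} for \eqn{|\xi| \le \sigma} and
#' \eqn{2\sigma|\xi| - \sigma^2} beyond (HB). All three are even and
#' convex with \eqn{\varphi(0) = 0}. The absolute value in LN keeps the
#' potential even for negative differences.
#'
#' @param spec a \linkS4class{PenaltySpec}.
#' @param xi numeric vector/array of intensity differences (NA passes
#'   through, marking absent neighbor pairs).
#' @param control optional per-element control values overriding the
#'   spec's global value (used by the similarity-driven tuning, where the
#'   control varies per pixel pair).
#' @return Penalty values, same shape as \code{xi}.
#' @export
penaltyValue <- function(spec, xi, control = NULL) {
  ctl <- .resolveControl(spec, xi, control)
  switch(spec@kind,
    QD = xi^2,
    LN = {
      if (any(ctl <= 0, na.rm = TRUE)) stop("LN control delta must be > 0")
      u <- abs(xi) / ctl
      ctl^2 * (u - log1p(u))
    },
    HB = {
      if (any(ctl <= 0, na.rm = TRUE)) stop("HB control sigma must be > 0")
      ax <- abs(xi)
      ifelse(ax <= ctl, xi^2, 2 * ctl * ax - ctl^2)
    })
}

#' Penalty first derivative
#'
#' \eqn{\varphi'(\xi)}: \eqn{2\xi} (QD); \eqn{\xi / (1 + |\xi|/\delta)}
#' (LN); \eqn{2\xi} below the knee and \eqn{2\sigma\,\mathrm{sign}(\xi)}
#' above (HB). Odd; its magnitude saturates at \eqn{K = \delta} (LN) and
#' \eqn{K = 2\sigma} (HB), the edge-preservation limit of a convex
#' non-quadratic penalty.
#'
#' @inheritParams penaltyValue
#' @return Derivative values, same shape as \code{xi}.
#' @export
penaltyDeriv <- function(spec, xi, control = NULL) {
  ctl <- .resolveControl(spec, xi, control)
  switch(spec@kind,
    QD = 2 * xi,
    LN = {
      if (any(ctl <= 0, na.rm = TRUE)) stop("LN control delta must be > 0")
      xi / (1 + abs(xi) / ctl)
    },
    HB = {
      if (any(ctl <= 0, na.rm = TRUE)) stop("HB control sigma must be > 0")
      ifelse(abs(xi) <= ctl, 2 * xi, 2 * ctl * sign(xi))
    })
}

#' Penalty curvature ratio
#'
#' \eqn{\psi(\xi) = \varphi'(\xi)/\xi}, extended continuously at
#' \eqn{\xi = 0} (QD: 2; LN: 1; HB: 2). Even, positive, nonincreasing in
#' \eqn{|\xi|}; it is the optimal quadratic-surrogate curvature: for any
#' expansion point \eqn{\xi_0},
#' \eqn{\varphi(\xi_0) + \varphi'(\xi_0)(\xi-\xi_0) +
#' \tfrac12\psi(\xi_0)(\xi-\xi_0)^2 \ge \varphi(\xi)}.
#'
#' @inheritParams penaltyValue
#' @return Curvature values, same shape as \code{xi}.
#' @export
penaltyCurvature <- function(spec, xi, control = NULL) {
  ctl <- .resolveControl(spec, xi, control)
  switch(spec@kind,
    QD = rep_len(2, length(xi)) + 0 * xi,  # keep shape and NA pattern
    LN = {
      if (any(ctl <= 0, na.rm = TRUE)) stop("LN control delta must be > 0")
      1 / (1 + abs(xi) / ctl)
    },
    HB = {
      if (any(ctl <= 0, na.rm = TRUE)) stop("HB control sigma must be > 0")
      ax <- abs(xi)
      ifelse(ax <= ctl, 2, 2 * ctl / ax)
    })
}
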