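# Internal helpers shared across modules.

# Directed 4-neighborhood offsets (row, col): north, south, west, east.
.NB_OFFSETS <- matrix(c(-1L, 0L,
                        1L, 0L,
                        0L, -1L,
                        0L, 1L),
                      ncol = 2L, byrow = TRUE,
                      dimnames = list(c("N", "S", "W", "E"), c("dr", "dc")))

#' @noRd
.isSquareMatrix <- function(x) is.matrix(x) && nrow(x) == ncol(x)

#' @noRd
.checkImage <- function(img, what = "image") {
  if (!is.matrix(img) || !is.numeric(img))
    stop(what, " must be a numeric matrix", call. = FALSE)
  if (nrow(img) != ncol(img))
    stop(what, " must be square", call. = FALSE)
  if (anyNA(img) || any(img < 0))
    stop(what, " must be nonnegative and free of NA", call. = FALSE)
  invisible(img)
}

# Replicate-pad a matrix by r pixels on every side.
#' @noRd
.padReplicate <- function(m, r) {
  if (r == 0L) return(m)
  n1 <- nrow(m); n2 <- ncol(m)
  ri <- c(rep(1L, r), seq_len(n1), rep(n1, r))
  ci <- c(rep(1L, r), seq_len(n2), rep(n2, r))
  m[ri, ci, drop = FALSE]
}

# Shift so that out[r, c] = m[r + dr, c + dc]; cells falling outside are NA
# (pad = "na") or clamped to the nearest border pixel (pad = "replicate").
#' @noRd
.shiftImage <- function(m, dr, dc, pad = c("na", "replicate")) {
  pad <- match.arg(pad)
  n1 <- nrow(m); n2 <- ncol(m)
  ri <- seq_len(n1) + dr
  ci <- seq_len(n2) + dc
  if (pad == "replicate") {
    ri <- pmin(pmax(ri, 1L), n1)
    ci <- pmin(pmax(ci, 1L), n2)
    m[ri, ci, drop = FALSE]
  } else {
    out <- matrix(NA_real_, n1, n2)
    okr <- ri >= 1L & ri <= n1
    okc <- ci >= 1L & ci <= n2
    out[okr, okc] <- m[ri[okr], ci[okc]]
    out
  }
}

# Sum of m over the (2r+1) x (2r+1) window centered at each interior pixel of
# a matrix already padded by >= r; returns the valid (unpadded) region.
#' @noRd
.boxSumValid <- function(mpad, r, nOut1, nOut2) {
  ii <- apply(mpad, 2L, cumsum)
  ii <- t(apply(ii, 1L, cumsum))
  ii <- rbind(0, cbind(0, ii))
  off1 <- (nrow(mpad) - nOut1) %/% 2L   # symmetric padding assumed
  off2 <- (ncol(mpad) - nOut2) %/% 2L
  r1 <- seq_len(nOut1) + off1
  c1 <- seq_len(nOut2) + off2
  top <- r1 - r; bot <- r1 + r; lef <- c1 - r; rig <- c1 + r
  ii[bot + 1L, rig + 1L, drop = FALSE] -
    ii[top, rig + 1L, drop = FALSE] -
    ii[bot + 1L, lef, drop = FALSE] +
    ii[top, lef, drop = FALSE]
}

# Evaluate expr with a temporary RNG state seeded by `seed`, restoring the
# caller's state afterwards.
#' @noRd
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

# Deterministic phase in [0, 2*pi) derived from an integer seed by
# golden-ratio hashing (no RNG state touched).
#' @noRd
.seedPhase <- function(seed, k) {
  x <- (as.double(seed) * c(0.6180339887498949, 0.7548776662466927,
                            0.8191725133961645)[k]) %% 1
  2 * pi * x
}
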