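# Shared fixtures, built lazily and cached for the whole run.

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixtureCache)) {
    assign(key, builder(), envir = .fixtureCache)
  }
  get(key, envir = .fixtureCache)
}

model16 <- function() cached("model16", function()
  buildSystemModel(16, 12, 16))
model32 <- function() cached("model32", function()
  buildSystemModel(32, 32, 32))
model64 <- function() cached("model64", function()
  buildSystemModel(64, 64, 64))
model8 <- function() cached("model8", function()
  buildSystemModel(8, 4, 8))

phantom32 <- function() cached("phantom32", function() makeBrainPhantom(32))
phantom64 <- function() cached("phantom64", function() makeBrainPhantom(64))

# Independent dense system matrix: per-pixel slab clipping of the
# parametric ray (a different construction from the chord-profile
# assembly inside buildSystemModel).
denseSystemOracle <- function(nBins, nAngles, n) {
  ang <- (seq_len(nAngles) - 1) * pi / nAngles
  Ho <- matrix(0, nBins * nAngles, n * n)
  tb <- seq_len(nBins) - (nBins + 1) / 2
  for (v in seq_len(nAngles)) {
    th <- ang[v]; w <- c(cos(th), sin(th)); d <- c(-sin(th), cos(th))
    for (b in seq_len(nBins)) {
      p0 <- tb[b] * w
      for (col in 1:n) for (row in 1:n) {
        ctr <- c(col - (n + 1) / 2, (n + 1) / 2 - row)
        lo <- -Inf; hi <- Inf; ok <- TRUE
        for (ax in 1:2) {
          if (abs(d[ax]) < 1e-14) {
            if (abs(p0[ax] - ctr[ax]) > 0.5) { ok <- FALSE; break }
          } else {
            s1 <- (ctr[ax] - 0.5 - p0[ax]) / d[ax]
            s2 <- (ctr[ax] + 0.5 - p0[ax]) / d[ax]
            lo <- max(lo, min(s1, s2)); hi <- min(hi, max(s1, s2))
          }
        }
        if (ok && hi > lo) Ho[(v - 1) * nBins + b, (col - 1) * n + row] <-
            hi - lo
      }
    }
  }
  Ho
}

# A small noisy scan shared by several recon tests.
scan32 <- function() cached("scan32", function()
  simulateScan(model32(), phantom32(), 6e4, seed = 11))

randImage <- function(n, seed) {
  set.seed(seed)
  matrix(runif(n * n, 0.2, 2), n, n)
}

# Golden-section minimizer for scalar unimodal functions.
goldenMin <- function(fn, lo, hi, tol = 1e-12, iters = 200) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- fn(c1); f2 <- fn(c2)
  for (i in seq_len(iters)) {
    if (f1 < f2) { b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - gr * (b - a); f1 <- fn(c1)
    } else { a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + gr * (b - a); f2 <- fn(c2) }
    if (b - a < tol * max(1, abs(a))) break
  }
  (a + b) / 2
}
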