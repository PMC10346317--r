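# Brute-force patch-difference oracle: explicit loops over the P patch
# pixels with replicate clamping at the borders.
bruteDeltaRho <- function(image, j, jp, r = 1L) {
  n1 <- nrow(image); n2 <- ncol(image)
  at <- function(rr, cc) image[min(max(rr, 1L), n1), min(max(cc, 1L), n2)]
  s <- 0
  for (dr in -r:r) for (dc in -r:r)
    s <- s + (at(j[1] + dr, j[2] + dc) - at(jp[1] + dr, jp[2] + dc))^2
  s
}

test_that("patch difference matches a brute-force loop on random images", {
  img <- randImage(8, seed = 21)
  for (j1 in 1:8) for (j2 in 1:8) {
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      jp <- c(j1, j2) + d
      if (any(jp < 1) || any(jp > 8)) next
      expect_equal(patchDifference(img, c(j1, j2), jp),
                   bruteDeltaRho(img, c(j1, j2), jp), tolerance = 1e-12)
    }
  }
  # symmetry and zero on identical patches
  expect_equal(patchDifference(img, c(3, 4), c(3, 5)),
               patchDifference(img, c(3, 5), c(3, 4)))
  expect_equal(patchDifference(matrix(2, 8, 8), c(4, 4), c(4, 5)), 0)
  # all 1s vs all 2s patches, P = 9
  img2 <- matrix(1, 9, 9); img2[, 6:9] <- 2
  expect_equal(patchDifference(img2, c(5, 2), c(5, 8)), 9)
  expect_error(patchDifference(img, c(0, 1), c(1, 1)), "grid")
})

test_that("similarity weights equal the brute-force exp(-drho/h^2) on random images", {
  img <- randImage(8, seed = 22)
  h <- 1.3
  sf <- patchSimilarity(img, h = h)
  W <- similarityWeights(sf)
  offs <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  for (k in 1:4) for (j1 in 1:8) for (j2 in 1:8) {
    jp <- c(j1, j2) + offs[[k]]
    if (any(jp < 1) || any(jp > 8)) {
      expect_true(is.na(W[j1, j2, k]))
    } else {
      expect_equal(W[j1, j2, k],
                   exp(-bruteDeltaRho(img, c(j1, j2), jp) / h^2),
                   tolerance = 1e-12)
    }
  }
  # symmetry: W_jj' = W_j'j  (N at j+S equals S at j)
  expect_equal(W[2:8, , 1], W[1:7, , 2])
  expect_equal(W[, 2:8, 3], W[, 1:7, 4])
})

test_that("uniform images give unit weights and w = 1; bandwidth must be positive", {
  sf <- patchSimilarity(matrix(3, 10, 10), h = 2)
  expect_true(all(similarityWeights(sf) == 1, na.rm = TRUE))
  expect_equal(meanSimilarity(sf), 1)
  # data-driven default bandwidth also survives a constant image
  expect_equal(meanSimilarity(patchSimilarity(matrix(3, 10, 10))), 1)
  expect_error(patchSimilarity(matrix(1, 8, 8), h = 0), "positive")
  # delta rho = h^2 gives exactly exp(-1)
  img <- matrix(0, 8, 8); img[, 5:8] <- 1
  dr <- patchDifference(img, c(4, 4), c(4, 5))
  sf2 <- patchSimilarity(img, h = sqrt(dr))
  expect_equal(similarityWeights(sf2)[4, 4, 4], exp(-1), tolerance = 1e-12)
})

test_that("roughness measures behave on constant, step, and random images", {
  cst <- matrix(5, 12, 12)
  expect_true(all(roughnessGradient(cst)@z == 0))
  expect_true(all(roughnessSD(cst)@z == 0))
  # vertical step: gradient maximal on the step columns
  st <- matrix(0, 12, 12); st[, 7:12] <- 2
  zg <- roughnessGradient(st)@z
  expect_true(all(zg[, c(6, 7)] == 1))       # central diff (2 - 0)/2
  expect_true(all(zg[, c(1:4, 10:12)] == 0))
  # transpose equivariance
  img <- randImage(9, seed = 31)
  expect_equal(roughnessGradient(t(img))@z, t(roughnessGradient(img)@z))
  # SD matches the direct per-pixel formula (divisor L-1 = 8)
  zsd <- roughnessSD(img)@z
  at <- function(rr, cc) img[min(max(rr, 1), 9), min(max(cc, 1), 9)]
  for (j1 in c(1, 4, 9)) for (j2 in c(1, 5, 9)) {
    vals <- c()
    for (dr in -1:1) for (dc in -1:1) vals <- c(vals, at(j1 + dr, j2 + dc))
    expect_equal(zsd[j1, j2], sqrt(sum((vals - mean(vals))^2) / 8),
                 tolerance = 1e-12)
  }
  # the documented window example: four 0s and five 1s
  w9 <- c(0, 0, 0, 0, 1, 1, 1, 1, 1)
  img9 <- matrix(w9, 3, 3)
  expect_equal(roughnessSD(img9)@z[2, 2],
               sqrt(sum((w9 - 5 / 9)^2) / 8), tolerance = 1e-12)
})

test_that("patch-similarity flatness is 1 on uniform images and lower at edges", {
  sfu <- patchSimilarity(matrix(2, 16, 16), h = 1)
  expect_true(all(roughnessPS(sfu)@z == 1))
  f <- makeTwoRegionPhantom(32, 4, 1)
  z <- roughnessPS(patchSimilarity(f))@z
  expect_true(all(z > 0 & z <= 1))
  edgePix <- z[16, 16 + 8]       # on the disc boundary
  flatPix <- z[16, 16]           # deep interior
  expect_lt(edgePix, flatPix)
})

test_that("Butterworth alpha hits its anchor points and monotone ordering", {
  img <- randImage(10, seed = 41)
  z <- roughnessSD(img)
  al <- butterworthAlpha(z, lambda = 40)       # r = 4
  expect_true(all(al >= -1 & al <= 1))
  # z = t maps exactly to 0
  z0 <- z; z0@z[] <- mean(z@z)
  expect_true(all(abs(butterworthAlpha(z0, 40)) < 1e-12))
  # monotone: sorting by oriented roughness sorts alpha identically
  ord <- order(z@z)
  expect_true(all(diff(al[ord]) <= 1e-12))
  # PS orientation: flat (z -> 1, t < 1) -> alpha -> +1; z -> 0 -> -1
  zp <- new("RoughnessField",
            z = matrix(c(1e-9 * 0.5, rep(0.5, 8), 1), 2, 5), measure = "PS")
  ap <- butterworthAlpha(zp, 40)
  expect_lt(ap[1, 1], -1 + 1e-6)
  expect_gt(ap[2, 5], 0.99)
  # identically-zero roughness is rejected
  zz <- new("RoughnessField", z = matrix(0, 4, 4), measure = "SD")
  expect_error(butterworthAlpha(zz, 40), "zero")
})

test_that("fine-tuned control follows delta0 (1 + W + alpha w) with tight bounds", {
  # exhaustive grid over W, alpha, w through handcrafted fields
  n <- 3
  for (wv in c(0.2, 0.6, 1)) for (al in c(-1, 0, 1)) for (Wv in c(0, 0.5, 1)) {
    Wf <- array(pmax(Wv, 1e-12), c(n, n, 4))
    field <- new("SimilarityField", W = Wf, w = max(wv, 1e-12), h = 1,
                 patchRadius = 1L)
    ctl <- fineTuneControl(0.2, field, matrix(al, n, n))
    expect_equal(controlValues(ctl)[1, 1, 1],
                 0.2 * (1 + max(Wv, 1e-12) + al * wv), tolerance = 1e-12)
  }
  # substitution checks from the tuning rule
  fld <- new("SimilarityField", W = array(1, c(2, 2, 4)), w = 1, h = 1,
             patchRadius = 1L)
  expect_equal(unique(as.vector(
    controlValues(fineTuneControl(0.3, fld, matrix(0, 2, 2))))), 0.6)
  expect_equal(unique(as.vector(
    controlValues(fineTuneControl(0.3, fld, matrix(1, 2, 2))))), 0.9)
  # bounds delta0 (1 - w) <= delta <= delta0 (2 + w) on a real image
  img <- randImage(12, seed = 51)
  sf <- patchSimilarity(img)
  al <- butterworthAlpha(roughnessSD(img), 40)
  d <- controlValues(fineTuneControl(0.1, sf, al))
  w <- meanSimilarity(sf)
  expect_gte(min(d, na.rm = TRUE), 0.1 * (1 - w) - 1e-12)
  expect_lte(max(d, na.rm = TRUE), 0.1 * (2 + w) + 1e-12)
  expect_true(all(d > 0, na.rm = TRUE))
  expect_error(fineTuneControl(0.1, sf, matrix(0, 3, 3)), "match")
})

test_that("edge pairs get smaller control than flat pairs on the two-region phantom", {
  # the tuning mechanism, directly on the noiseless fixture for each measure
  f <- makeTwoRegionPhantom(48, 4, 1)
  truthEdge <- abs(f - sdplpet:::.shiftImage(f, 0, 1, "replicate")) +
    abs(f - sdplpet:::.shiftImage(f, 1, 0, "replicate"))
  sf <- patchSimilarity(f)
  delta0 <- 0.1
  for (ms in c("GR", "SD", "PS")) {
    z <- switch(ms, GR = roughnessGradient(f), SD = roughnessSD(f),
                PS = roughnessPS(sf))
    ctl <- fineTuneControl(delta0, sf, butterworthAlpha(z, 40))
    d <- controlValues(ctl)
    nearEdge <- truthEdge > 0
    far <- !nearEdge &
      !sdplpet:::.shiftImage(nearEdge + 0, 0, 1, "replicate") &
      !sdplpet:::.shiftImage(nearEdge + 0, 0, -1, "replicate") &
      !sdplpet:::.shiftImage(nearEdge + 0, 1, 0, "replicate") &
      !sdplpet:::.shiftImage(nearEdge + 0, -1, 0, "replicate")
    dEdge <- mean(d[rep(nearEdge, 4)], na.rm = TRUE)
    dFlat <- mean(d[rep(far, 4)], na.rm = TRUE)
    expect_lt(dEdge, delta0)
    expect_gt(dFlat, delta0)
  }
})
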