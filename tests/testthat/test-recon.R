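test_that("initialization matches total counts and fills accumulators", {
  m <- model16()
  set.seed(61)
  g <- matrix(rpois(12 * 16, 5), 12, 16)
  part <- makeSubsets(m, 4)
  st <- initReconState(g, m, part)
  expect_equal(sum(forwardProject(m, st$f)), sum(g), tolerance = 1e-12)
  expect_true(all(st$f > 0))
  expect_identical(dim(st$A), c(256L, 4L))
  # C-update normalization: complete data sums to the measured counts
  # on every visited ray (checked through a dense C matrix)
  H <- as.matrix(systemMatrix(m))
  fvec <- as.vector(st$f)
  proj <- as.numeric(H %*% fvec)
  gvec <- as.vector(t(g))
  for (q in 1:4) {
    rays <- raySubsets(part)[[q]]
    ratio <- ifelse(proj[rays] > 0, gvec[rays] / proj[rays], 0)
    C <- H[rays, , drop = FALSE] * outer(ratio, fvec)
    expect_equal(rowSums(C)[gvec[rays] > 0],
                 gvec[rays][gvec[rays] > 0], tolerance = 1e-9)
    # accumulators equal the dense column sums
    expect_equal(st$A[, q], colSums(C), tolerance = 1e-12)
  }
  expect_error(initReconState(matrix(0, 12, 16), m, part), "zero")
})

test_that("one-pixel toys reproduce the closed-form C and ML updates", {
  # H = [1], f = 3, g = 6: accumulator = 3 * (1 * 6/3) = 6
  m1 <- buildSystemModel(1, 1, 1)
  expect_equal(as.numeric(systemMatrix(m1)), 1)
  part <- makeSubsets(m1, 1)
  st <- list(f = matrix(3, 1, 1), A = matrix(0, 1, 1),
             sens = 1, partition = part, eps = 1e-12)
  st <- cosemCUpdate(st, m1, matrix(6, 1, 1), 1)
  expect_equal(st$A[1, 1], 6)
  # EM-ML on the same toy: f0 = 5 (count-matched), g = 5 is a fixed point
  r <- runEMML(matrix(5, 1, 1), m1, 3)
  expect_equal(estimate(r)[1, 1], 5, tolerance = 1e-12)
})

test_that("the pixel quadratic takes the positive root with linear fallback", {
  expect_equal(solvePixelQuadratic(1, 0, -4), 2)
  expect_equal(solvePixelQuadratic(0, 2, -4), 2)
  expect_equal(solvePixelQuadratic(2, 3, -2), 0.5)
  expect_equal(solvePixelQuadratic(c(1, 0), c(0, 2), c(-4, -4)), c(2, 2))
  expect_error(solvePixelQuadratic(-1, 0, 0), ">= 0")
  expect_error(solvePixelQuadratic(1, 0, 1), "<= 0")
  expect_error(solvePixelQuadratic(0, -1, -1), "root")
  # vectorized roots match polyroot on random coefficients
  set.seed(71)
  a <- runif(50, 0.1, 3); b <- runif(50, -3, 3); c <- -runif(50, 0, 3)
  f <- solvePixelQuadratic(a, b, c)
  expect_true(all(abs(a * f^2 + b * f + c) < 1e-9))
  expect_true(all(f >= 0))
})

test_that("COSEM with one subset and lambda 0 reproduces EM-ML iterates", {
  m <- model8()
  ph <- matrix(1, 8, 8)
  ph[(row(ph) - 4.5)^2 + (col(ph) - 4.5)^2 <= 4] <- 3
  ph[1, ] <- 0
  scan <- simulateScan(m, ph, 2000, seed = 5)
  for (it in 1:5) {
    rc <- runCosem(scan$sinogram, m, penaltySpec("QD"), lambda = 0,
                   subsets = 1, iterations = it, keepHistory = FALSE)
    re <- runEMML(scan$sinogram, m, it, keepHistory = FALSE)
    expect_lt(max(abs(estimate(rc) - estimate(re))), 1e-12 * max(estimate(re)))
  }
})

test_that("EM-ML log-likelihood is nondecreasing and counts are conserved", {
  m <- model16()
  ph <- makeTwoRegionPhantom(16, 4, 1)
  ph[(row(ph) - 8.5)^2 + (col(ph) - 8.5)^2 > 49] <- 0
  scan <- simulateScan(m, ph, 2e4, seed = 9)
  r <- runEMML(scan$sinogram, m, 40)
  h <- objectiveHistory(r)
  expect_true(all(diff(h) >= -1e-9 * abs(h[-length(h)])))
  # at (near) stationarity the predicted total matches the measured total
  expect_equal(sum(forwardProject(m, estimate(r))), sum(scan$sinogram),
               tolerance = 1e-6)
  # noiseless consistent data: Hf = g is a fixed point
  g0 <- forwardProject(m, estimate(r))
  r2 <- runEMML(g0, m, 1, keepHistory = FALSE)
  expect_equal(sum(forwardProject(m, estimate(r2))), sum(g0),
               tolerance = 1e-9)
})

test_that("lambda = 0 pixel update reduces to the COSEM-ML M-step", {
  m <- model16()
  set.seed(81)
  g <- matrix(rpois(12 * 16, 8), 12, 16)
  part <- makeSubsets(m, 2)
  st <- initReconState(g, m, part)
  st2 <- cosemFUpdate(st, penaltySpec("LN", 0.5), lambda = 0)
  expect_equal(as.vector(st2$f),
               pmax(rowSums(st$A) / st$sens, st$eps), tolerance = 1e-12)
})

test_that("every pixel update minimizes its 1-D SPS surrogate (golden-section oracle)", {
  m <- model8()
  part1 <- makeSubsets(m, 1)
  offs <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  worst <- 0
  for (case in 1:20) {
    f <- randImage(8, seed = 100 + case)
    set.seed(200 + case)
    g <- matrix(rpois(4 * 8, 6), 4, 8)
    pen <- if (case %% 3 == 0) penaltySpec("HB", 0.4) else
      if (case %% 3 == 1) penaltySpec("LN", 0.6) else penaltySpec("QD")
    lam <- c(0.5, 2, 8)[1 + case %% 3]
    st <- initReconState(g, m, part1)
    st$f <- f
    st <- cosemCUpdate(st, m, g, 1)
    new <- cosemFUpdate(st, pen, lam)$f
    A <- rowSums(st$A)
    for (j1 in 1:8) for (j2 in 1:8) {
      jj <- (j2 - 1) * 8 + j1
      # 1-D surrogate: sens*t - A*log t + lam * sum psi (2t - fo - fo')^2
      nbv <- c()
      for (d in offs) {
        p <- c(j1, j2) + d
        if (all(p >= 1 & p <= 8)) nbv <- c(nbv, f[p[1], p[2]])
      }
      xi0 <- f[j1, j2] - nbv
      ps <- penaltyCurvature(pen, xi0)
      sur <- function(t) st$sens[jj] * t -
        (if (A[jj] > 0) A[jj] * log(t) else 0) +
        lam * sum(ps * (2 * t - f[j1, j2] - nbv)^2)
      opt <- goldenMin(sur, 1e-8, max(f) * 3 + 5)
      worst <- max(worst, abs(new[j1, j2] - opt) / max(opt, 1e-8))
    }
  }
  expect_lt(worst, 1e-6)
})

test_that("pixel updates never increase the summed per-pixel surrogate", {
  m <- model16()
  set.seed(91)
  g <- matrix(rpois(12 * 16, 7), 12, 16)
  part <- makeSubsets(m, 2)
  st <- initReconState(g, m, part)
  st$f <- randImage(16, seed = 92)
  st <- cosemCUpdate(st, m, g, 1)
  pen <- penaltySpec("LN", 0.3); lam <- 3
  surTotal <- function(f) {
    A <- rowSums(st$A)
    val <- sum(st$sens * as.vector(f)) -
      sum(ifelse(A > 0, A * log(as.vector(f)), 0))
    for (k in 1:4) {
      nb <- sdplpet:::.shiftImage(st$f, sdplpet:::.NB_OFFSETS[k, 1],
                                  sdplpet:::.NB_OFFSETS[k, 2], "na")
      ps <- penaltyCurvature(pen, st$f - nb)
      val <- val + lam * sum(ps * (2 * f - st$f - nb)^2, na.rm = TRUE)
    }
    val
  }
  before <- surTotal(st$f)
  after <- surTotal(cosemFUpdate(st, pen, lam)$f)
  expect_lte(after, before + 1e-9 * abs(before))
})

test_that("fixed-parameter PL monotonically decreases the penalized energy", {
  scan <- scan32()
  for (pk in list(penaltySpec("LN", 0.1), penaltySpec("HB", 0.06),
                  penaltySpec("QD"))) {
    r <- runCosem(scan$sinogram, model32(), pk, lambda = 20, subsets = 1,
                  iterations = 15)
    h <- objectiveHistory(r)
    expect_true(all(diff(h) <= 1e-9 * abs(h[-length(h)])),
                info = pk@kind)
  }
})

test_that("penalized energy matches a naive double-loop evaluation", {
  m <- model8()
  f <- randImage(8, seed = 71)
  set.seed(72)
  g <- matrix(rpois(4 * 8, 5), 4, 8)
  pen <- penaltySpec("LN", 0.5); lam <- 2.5
  # naive: data fit plus 2 lambda sum over directed pairs
  H <- as.matrix(systemMatrix(m))
  proj <- as.numeric(H %*% as.vector(f))
  gvec <- as.vector(t(g))
  naive <- sum(proj) - sum(ifelse(gvec > 0, gvec * log(proj), 0))
  offs <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  for (j1 in 1:8) for (j2 in 1:8) for (d in offs) {
    p <- c(j1, j2) + d
    if (all(p >= 1 & p <= 8))
      naive <- naive + 2 * lam * penaltyValue(pen, f[j1, j2] - f[p[1], p[2]])
  }
  expect_equal(penalizedObjective(f, g, m, pen, lam), naive,
               tolerance = 1e-10)
  # lambda = 0 reduction and uniform-image zero penalty
  expect_equal(penalizedObjective(f, g, m, pen, 0),
               sum(proj) - sum(ifelse(gvec > 0, gvec * log(proj), 0)),
               tolerance = 1e-12)
  u <- matrix(1.5, 8, 8)
  expect_equal(penalizedObjective(u, g, m, pen, 7),
               penalizedObjective(u, g, m, pen, 0), tolerance = 1e-12)
  # zero prediction with positive counts signals infinite energy
  z <- matrix(0, 8, 8); z[1, 1] <- 1e-30
  expect_true(is.infinite(penalizedObjective(0 * f, g, m, pen, 1)))
})

test_that("reconstruction iterates stay strictly positive", {
  scan <- scan32()
  r <- runCosem(scan$sinogram, model32(), penaltySpec("LN", 0.05),
                lambda = 40, subsets = 4, iterations = 5,
                keepHistory = FALSE)
  expect_true(all(estimate(r) > 0))
  rml <- runCosem(scan$sinogram, model32(), lambda = 0, subsets = 4,
                  iterations = 5, keepHistory = FALSE)
  expect_true(all(estimate(rml) > 0))
})

test_that("SDPL refreshes the control field per outer iteration and labels runs", {
  scan <- scan32()
  r <- runCosem(scan$sinogram, model32(), penaltySpec("LN", 0.1),
                lambda = 20, subsets = 4, iterations = 3, sdpl = TRUE,
                measure = "PS", keepHistory = FALSE)
  expect_s4_class(r@control, "ControlField")
  expect_identical(r@method, "SDPL-LN-PS")
  expect_identical(runCosem(scan$sinogram, model32(),
                            penaltySpec("HB", 0.06), lambda = 10,
                            subsets = 2, iterations = 2,
                            keepHistory = FALSE)@method, "PL-HB")
  expect_error(runCosem(scan$sinogram, model32(), penaltySpec("QD"),
                        lambda = 10, sdpl = TRUE), "LN and HB")
  expect_error(runCosem(scan$sinogram, model32(), penaltySpec("LN", 0.1),
                        lambda = 0, sdpl = TRUE), "lambda")
})
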