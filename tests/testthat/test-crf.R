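# Feature functions, wall prior and the total energy.

test_that("spatial and temporal continuity features are scaled squares", {
  M <- 256
  expect_equal(fSpatial(100, 100, M), 0)
  expect_equal(fSpatial(M, 0, M), 1)
  expect_equal(fSpatial(37, 91, M), fSpatial(91, 37, M))
  expect_equal(fTemporal(10, 10 + M / 2, M), 0.25)
  expect_equal(fTemporal(80, 70, M), fTemporal(70, 80, M))
})

test_that("systolic feature penalises growth before tES, shrinkage after", {
  expect_equal(fSystole(110, 100, t = 5, tES = 8), 1)  # growth in systole
  expect_equal(fSystole(90, 100, t = 5, tES = 8), 0)
  expect_equal(fSystole(90, 100, t = 10, tES = 8), 1)  # shrink in diastole
  expect_equal(fSystole(110, 100, t = 10, tES = 8), 0)
})

test_that("wall-intensity features sample at the offset and take |diff|", {
  M <- 32
  dT <- rep(0, M); dPrev <- rep(0, M)
  dT[20 - 2 + 1] <- 10; dPrev[18 - 2 + 1] <- 14
  expect_equal(fWallIntensityTemporal(dT, dPrev, 20, 18, 2, "outer"), 4)
  expect_equal(fWallIntensityTemporal(dT, dT, 20, 20, 2, "outer"), 0)
  # adding a constant to both rows changes nothing
  expect_equal(fWallIntensityTemporal(dT + 5, dPrev + 5, 20, 18, 2, "outer"), 4)
  d <- rep(0, M); d[10 + 2 + 1] <- 100; d[12 + 2 + 1] <- 92
  expect_equal(fWallIntensitySpatial(d, 10, 12, 2, "inner"), 8)
  expect_true(fWallIntensitySpatial(d, 12, 10, 2, "inner") >= 0)
  # out-of-range samples clamp to the valid bin range
  expect_equal(fWallIntensityTemporal(dT, dPrev, 0, 0, 2, "outer"),
               abs(dT[1] - dPrev[1]))
})

test_that("fitWallPrior builds a floored, normalised thickness histogram", {
  mk <- function(deltas) {
    inner <- matrix(40L, 4, length(deltas))
    outer <- inner + matrix(as.integer(deltas), 4, length(deltas),
                            byrow = TRUE)
    RadialSegmentation(inner, outer, matrix(0, length(deltas), 2), 128)
  }
  pr <- fitWallPrior(mk(rep(40, 5)), floor = 1e-6)
  expect_equal(sum(wallPmf(pr)), 1)
  expect_gt(wallPmf(pr)[41], 0.999)
  # two equally frequent thicknesses share the mass
  pr2 <- fitWallPrior(mk(c(10, 20, 10, 20)), floor = 1e-6)
  expect_equal(wallPmf(pr2)[11], wallPmf(pr2)[21])
  expect_gt(wallPmf(pr2)[11], 0.49)
  expect_true(all(wallPmf(pr2) > 0))
  bad <- RadialSegmentation(matrix(50L, 4, 1), matrix(40L, 4, 1),
                            matrix(0, 1, 2), 128)
  expect_error(fitWallPrior(bad), "outer")
})

test_that("fCrossRatio is the negative log prior mass", {
  prior <- fitWallPrior(
    RadialSegmentation(matrix(40L, 8, 1), matrix(80L, 8, 1),
                       matrix(0, 1, 2), 128), floor = 1e-6)
  expect_lt(fCrossRatio(40, 80, prior), 2e-4)     # -log(~1)
  expect_equal(fCrossRatio(40, 50, prior), 13.8155, tolerance = 1e-3)
  unif <- new("WallPrior", pmf = rep(1 / 64, 64), floor = 1e-6)
  expect_equal(fCrossRatio(0, 63, unif), log(64))
  expect_error(fCrossRatio(50, 40, prior), "inner")
})

test_that("fWallVariance follows the printed divisor and the count variant", {
  d <- c(8, 12, rep(0, 30))
  expect_equal(fWallVariance(0, 1, d, "literal"), 208)  # divisor W = 1
  expect_equal(fWallVariance(0, 1, d, "count"), 4)      # conventional var
  # constant row is NOT zero under the W divisor: 7 summands, mean 35/6
  expect_equal(fWallVariance(3, 9, rep(5, 32), "literal"), 175 / 216,
               tolerance = 1e-12)
  expect_equal(fWallVariance(3, 9, rep(5, 32), "count"), 0)
  # count variant is shift invariant; the literal one shifts
  expect_equal(fWallVariance(0, 1, d + 3, "count"),
               fWallVariance(0, 1, d, "count"))
  expect_error(fWallVariance(5, 5, d), "positive")
})

test_that("total energy matches an independent clique-by-clique sum", {
  N <- 4L; M <- 8L; T <- 2L
  set.seed(31)
  lps <- randomLps(N, M, T, seed = 31)
  D <- lpData(lps)
  maps <- randomEdgeMaps(N, M, T, seed = 32)
  params <- tinyParams(M, seed = 33, minWall = 1, beamSpatial = M,
                       beamTemporal = M, tES = 1)
  prior <- uniformPrior(M)
  th <- theta(params)
  inner <- matrix(c(1L, 2L, 1L, 3L, 2L, 2L, 1L, 2L), N, T)
  outer <- matrix(c(4L, 5L, 6L, 5L, 6L, 7L, 5L, 4L), N, T)
  seg <- RadialSegmentation(inner, outer, matrix(0, T, 2), M)

  # independent recomputation with explicit arithmetic
  eps <- params@epsRho
  cl <- function(r) pmin(pmax(r, 0), M - 1)
  E <- 0
  for (t in 1:T) for (n in 1:N) {
    for (kind in c("inner", "outer")) {
      b <- if (kind == "inner") inner else outer
      sgn <- if (kind == "outer") -1 else 1
      nm1 <- if (n == 1) N else n - 1
      E <- E + th[paste0(kind, "Edge")] * maps[[kind]][n, b[n, t] + 1, t] +
        th[paste0(kind, "Spatial")] * ((b[n, t] - b[nm1, t]) / M)^2 +
        th[paste0(kind, "IntensitySpatial")] *
          abs(D[n, cl(b[n, t] + sgn * eps) + 1, t] -
              D[n, cl(b[nm1, t] + sgn * eps) + 1, t])
      if (t == 2) {
        grow <- if ((t - 1) < params@tES) b[n, 2] > b[n, 1] else
          b[n, 2] < b[n, 1]
        E <- E + th[paste0(kind, "Temporal")] * ((b[n, 2] - b[n, 1]) / M)^2 +
          th[paste0(kind, "Systole")] * as.numeric(grow) +
          th[paste0(kind, "IntensityTemporal")] *
            abs(D[n, cl(b[n, 2] + sgn * eps) + 1, 2] -
                D[n, cl(b[n, 1] + sgn * eps) + 1, 1])
      }
    }
    w <- D[n, (inner[n, t]:outer[n, t]) + 1, t]
    W <- outer[n, t] - inner[n, t]
    mu <- sum(w) / W
    E <- E + th["crossRatio"] * (-log(wallPmf(prior)[W + 1])) +
      th["wallVariance"] * sum((w - mu)^2) / W
  }
  expect_equal(totalEnergy(seg, lps, params, maps, prior), unname(E))
  # linear in theta
  p2 <- params; p2@theta <- 2 * th
  expect_equal(totalEnergy(seg, lps, p2, maps, prior),
               2 * totalEnergy(seg, lps, params, maps, prior))
  # all-zero features give zero energy
  lps0 <- new("LogPolarSequence", data = array(0, c(N, M, T)),
              centres = matrix(0, T, 2), rInit = 50)
  maps0 <- list(inner = array(0, c(N, M, T)), outer = array(0, c(N, M, T)))
  seg0 <- RadialSegmentation(matrix(2L, N, T), matrix(2L, N, T),
                             matrix(0, T, 2), M)
  expect_equal(totalEnergy(seg0, lps0, params, maps0, prior = NULL), 0)
})

test_that("energy is invariant under simultaneous angular rotation", {
  N <- 6L; M <- 10L; T <- 2L
  lps <- randomLps(N, M, T, seed = 41)
  maps <- randomEdgeMaps(N, M, T, seed = 42)
  params <- tinyParams(M, seed = 43, minWall = 1)
  prior <- uniformPrior(M)
  set.seed(44)
  inner <- matrix(sample(0:4, N * T, TRUE), N, T)
  outer <- inner + matrix(sample(1:4, N * T, TRUE), N, T)
  seg <- RadialSegmentation(inner, outer, matrix(0, T, 2), M)
  e1 <- totalEnergy(seg, lps, params, maps, prior)
  rot <- c(2:N, 1)
  lps2 <- new("LogPolarSequence", data = lpData(lps)[rot, , , drop = FALSE],
              centres = centres(lps), rInit = 50)
  maps2 <- list(inner = maps$inner[rot, , , drop = FALSE],
                outer = maps$outer[rot, , , drop = FALSE])
  seg2 <- RadialSegmentation(inner[rot, ], outer[rot, ],
                             matrix(0, T, 2), M)
  e2 <- totalEnergy(seg2, lps2, params, maps2, prior)
  expect_equal(e1, e2)
})

test_that("satisfiesConstraints checks beams, seam and wall", {
  M <- 64
  params <- crfParameters(minWall = 5, beamSpatial = 2, beamTemporal = 10)
  inner <- matrix(20L, 8, 3); outer <- matrix(30L, 8, 3)
  seg <- RadialSegmentation(inner, outer, matrix(0, 3, 2), M)
  expect_true(satisfiesConstraints(seg, params))
  bad <- inner; bad[1, 1] <- 26L   # violates the (8, 1) seam bound
  expect_false(satisfiesConstraints(
    RadialSegmentation(bad, outer, matrix(0, 3, 2), M), params))
  thin <- RadialSegmentation(inner, inner + 2L, matrix(0, 3, 2), M)
  expect_false(satisfiesConstraints(thin, params))
  jump <- inner; jump[, 2] <- 35L  # temporal jump of 15 > 10
  expect_false(satisfiesConstraints(
    RadialSegmentation(jump, jump + 10L, matrix(0, 3, 2), M), params))
})
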