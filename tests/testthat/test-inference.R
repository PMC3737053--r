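# Belief propagation against exact oracles: the ring DP on single frames,
# exhaustive enumeration on tiny joint instances, and the structural
# guarantees (constraints, determinism, energy improvement).

test_that("normalizeMessage zeroes the minimum and preserves argmins", {
  expect_equal(normalizeMessage(c(3, 5, 4)), c(0, 2, 1))
  expect_equal(normalizeMessage(c(0, 2, 1)), c(0, 2, 1))   # idempotent
  set.seed(51)
  v <- runif(20)
  expect_equal(which.min(normalizeMessage(v)), which.min(v))
  expect_error(normalizeMessage(rep(Inf, 4)), "finite")
})

test_that("single-frame spatial-only inference equals the ring DP oracle", {
  N <- 16L; M <- 32L
  for (i in 1:4) {
    maps <- randomEdgeMaps(N, M, 1, seed = 60 + i)
    lps <- randomLps(N, M, 1, seed = 70 + i)
    th <- stats::setNames(rep(0, 14), thetaNames())
    th["innerEdge"] <- 1; th["innerSpatial"] <- 0.8
    params <- crfParameters(theta = th, beamSpatial = 2, beamTemporal = 5,
                            minWall = 1, tES = 1)
    seg <- runInference(lps, params, edgeMaps = maps, contours = "inner")
    oracle <- ringDPOracle(maps$inner[, , 1], 0.8, beam = 2)
    expect_identical(unname(innerBins(seg)[, 1]), oracle$bins)
    recordSegmentation(seg, params)
  }
})

test_that("tiny joint instances reach the exhaustive optimum", {
  hits <- 0
  for (i in 1:6) {
    inst <- tinyInstance(1000 + i)
    bf <- bruteForceSegment(inst$lps, inst$params, inst$prior, inst$maps)
    bp <- runInference(inst$lps, inst$params, prior = inst$prior,
                       edgeMaps = inst$maps)
    eBF <- totalEnergy(bf, inst$lps, inst$params, inst$maps, inst$prior)
    eBP <- totalEnergy(bp, inst$lps, inst$params, inst$maps, inst$prior)
    expect_equal(attr(bf, "energy"), eBF, tolerance = 1e-9)
    expect_true(satisfiesConstraints(bp, inst$params))
    expect_true(eBP >= eBF - 1e-9)
    if (abs(eBP - eBF) < 1e-9) hits <- hits + 1
    recordSegmentation(bp, inst$params)
  }
  expect_gte(hits, 5)
})

test_that("frustrated random-noise instances stay within the loopy-BP band", {
  # uniform-noise observations with random weights are adversarial for
  # loopy message passing; inference must stay feasible and never lose to
  # the oracle, though it may miss the exact optimum on such inputs
  N <- 3L; M <- 5L; T <- 2L
  for (i in 1:4) {
    lps <- randomLps(N, M, T, seed = 100 + i)
    maps <- randomEdgeMaps(N, M, T, seed = 200 + i)
    params <- tinyParams(M, seed = 300 + i, minWall = 1, beamSpatial = 2,
                         beamTemporal = M, tES = 1)
    prior <- uniformPrior(M)
    bf <- bruteForceSegment(lps, params, prior, maps)
    bp <- runInference(lps, params, prior = prior, edgeMaps = maps)
    expect_true(satisfiesConstraints(bp, params))
    expect_gte(totalEnergy(bp, lps, params, maps, prior),
               attr(bf, "energy") - 1e-9)
  }
})

test_that("brute force beats random feasible configurations", {
  N <- 3L; M <- 5L; T <- 2L
  lps <- randomLps(N, M, T, seed = 401)
  maps <- randomEdgeMaps(N, M, T, seed = 402)
  params <- tinyParams(M, seed = 403, minWall = 1, beamSpatial = 2,
                       beamTemporal = M)
  prior <- uniformPrior(M)
  bf <- bruteForceSegment(lps, params, prior, maps)
  eBF <- attr(bf, "energy")
  set.seed(404)
  worse <- 0
  for (i in 1:200) {
    inner <- matrix(sample(0:(M - 2), N * T, TRUE), N, T)
    outer <- matrix(NA_integer_, N, T)
    for (j in seq_len(N * T))
      outer[j] <- sample(inner[j] + 1:(M - 1 - inner[j]), 1)
    seg <- RadialSegmentation(inner, outer, centres(lps), M)
    if (!satisfiesConstraints(seg, params)) next
    expect_gte(totalEnergy(seg, lps, params, maps, prior), eBF - 1e-9)
    worse <- worse + 1
  }
  expect_gt(worse, 10)   # the random draw actually produced feasible cases
  expect_error(bruteForceSegment(randomLps(8, 16, 3), tinyParams(16), cap = 1e6),
               "cap")
})

test_that("inference is deterministic and improves on a flat initialisation", {
  N <- 8L; M <- 16L; T <- 3L
  lps <- randomLps(N, M, T, seed = 501)
  maps <- randomEdgeMaps(N, M, T, seed = 502)
  params <- tinyParams(M, seed = 503, minWall = 2, beamSpatial = 2,
                       beamTemporal = 6, tES = 1)
  prior <- uniformPrior(M)
  s1 <- runInference(lps, params, prior = prior, edgeMaps = maps)
  s2 <- runInference(lps, params, prior = prior, edgeMaps = maps)
  expect_identical(innerBins(s1), innerBins(s2))
  expect_identical(outerBins(s1), outerBins(s2))
  expect_true(satisfiesConstraints(s1, params))
  flat <- RadialSegmentation(matrix(M %/% 3, N, T),
                             matrix(M %/% 3 + params@minWall + 2, N, T),
                             centres(lps), M)
  expect_lte(totalEnergy(s1, lps, params, maps, prior),
             totalEnergy(flat, lps, params, maps, prior))
  recordSegmentation(s1, params)
})

test_that("angular closure holds at the seam", {
  N <- 12L; M <- 24L; T <- 2L
  lps <- randomLps(N, M, T, seed = 601)
  maps <- randomEdgeMaps(N, M, T, seed = 602)
  params <- tinyParams(M, seed = 603, minWall = 2, beamSpatial = 2,
                       beamTemporal = 8, tES = 1)
  seg <- runInference(lps, params, prior = uniformPrior(M), edgeMaps = maps)
  for (b in list(innerBins(seg), outerBins(seg)))
    expect_true(all(abs(b[1, ] - b[N, ]) <= params@beamSpatial))
})

test_that("wall infeasibility is reported with advice", {
  lps <- randomLps(4, 6, 1, seed = 701)
  params <- tinyParams(6, minWall = 10)
  expect_error(runInference(lps, params), "thin")
})
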