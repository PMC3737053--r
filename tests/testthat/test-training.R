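# Landmark errors and Powell weight fitting.

test_that("landmark error matches analytic distances", {
  ang <- 2 * pi * (0:255) / 256
  r20 <- cbind(20 * cos(ang), 20 * sin(ang))
  r24 <- cbind(24 * cos(ang), 24 * sin(ang))
  expect_equal(landmarkError(r20, r20), 0)
  expect_equal(landmarkError(r20, r24, spacing = 1), 4, tolerance = 0.01)
  expect_equal(landmarkError(r20, r24, spacing = 1.25), 5, tolerance = 0.01)
  expect_error(landmarkError(r20[0, ], r24), "empty")
})

# a small training problem: one phantom-like sequence with precomputed
# edge maps derived from the truth (peaked costs off the true contours)
.trainFixture <- function(seed = 111, N = 16L, M = 32L, T = 3L) {
  set.seed(seed)
  inner <- matrix(12L + sample(-1:1, N * T, TRUE), N, T)
  outer <- inner + 6L
  D <- array(0, c(N, M, T))
  for (t in 1:T) for (n in 1:N) {
    row <- ifelse(0:(M - 1) < inner[n, t], 0.9,
                  ifelse(0:(M - 1) < outer[n, t], 0.2, 0.55))
    D[n, , t] <- row + rnorm(M, 0, 0.02)
  }
  mkMap <- function(edge) {
    a <- array(0, c(N, M, T))
    for (t in 1:T) for (n in 1:N) {
      cost <- 1 - exp(-((0:(M - 1)) - edge[n, t])^2 / 8) +
        abs(rnorm(M, 0, 0.03))
      cost <- cost - min(cost)
      a[n, , t] <- cost / sum(cost)
    }
    a
  }
  truth <- RadialSegmentation(inner, outer, matrix(0, T, 2), M)
  lps <- new("LogPolarSequence", data = D, centres = matrix(0, T, 2),
             rInit = 12)
  list(lps = lps, truth = truth,
       edgeMaps = list(inner = mkMap(inner), outer = mkMap(outer)),
       prior = fitWallPrior(truth, M = M),
       params = crfParameters(tES = 1, epsRho = 1, beamSpatial = 2,
                              beamTemporal = 6, minWall = 3))
}

test_that("powellFit only accepts improving steps within its budget", {
  fx <- .trainFixture()
  problems <- list(list(lps = fx$lps, truth = fx$truth,
                        edgeMaps = fx$edgeMaps))
  theta0 <- stats::setNames(rep(1, 14), thetaNames())
  theta0["innerSpatial"] <- 25   # deliberately detuned start
  fit <- powellFit(problems, fx$params, fx$prior, theta0 = theta0,
                   lambda = 0, maxEvals = 50)
  expect_lte(fit$evals, 50)
  expect_true(all(diff(fit$trace) <= 1e-12))   # non-increasing
  expect_lte(fit$objective, fit$trace[1])
  expect_true(all(theta(fit$params) > 0))
  expect_error(powellFit(problems, fx$params, fx$prior,
                         theta0 = stats::setNames(rep(-1, 14), thetaNames())),
               "positive")
})

test_that("the log-theta regularizer shrinks an uninformative weight", {
  fx <- .trainFixture()
  problems <- list(list(lps = fx$lps, truth = fx$truth,
                        edgeMaps = fx$edgeMaps))
  # tES = T so the systole family never fires backwards motion on this
  # all-but-static truth; its weight carries no error signal
  p <- fx$params
  fit0 <- powellFit(problems, p, fx$prior, lambda = 0, maxEvals = 40)
  fitR <- powellFit(problems, p, fx$prior, lambda = 0.05, maxEvals = 40)
  expect_lte(sum(log(theta(fitR$params))), sum(log(theta(fit0$params))) + 1e-9)
})

test_that("training treats inference as a black box over its contours", {
  # the objective changes only through the inferred segmentation: two
  # theta vectors that induce the same argmin give identical errors
  fx <- .trainFixture()
  problems <- list(list(lps = fx$lps, truth = fx$truth,
                        edgeMaps = fx$edgeMaps))
  th <- stats::setNames(rep(1, 14), thetaNames())
  o1 <- trainingObjective(th, problems, fx$params, fx$prior, lambda = 0)
  o2 <- trainingObjective(2 * th, problems, fx$params, fx$prior, lambda = 0)
  s1 <- runInference(fx$lps, {p <- fx$params; p@theta <- th; p},
                     prior = fx$prior, edgeMaps = fx$edgeMaps)
  s2 <- runInference(fx$lps, {p <- fx$params; p@theta <- 2 * th; p},
                     prior = fx$prior, edgeMaps = fx$edgeMaps)
  if (identical(innerBins(s1), innerBins(s2)) &&
      identical(outerBins(s1), outerBins(s2)))
    expect_equal(o1, o2)
  expect_true(is.finite(o1))
})
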