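# Shared fixtures and independent oracles for the test suite. Everything
# is generated in code under fixed seeds; no binary fixtures.

# random log-polar "observation" with uniform noise intensities
randomLps <- function(N, M, T, seed = 1, centre = c(0, 0)) {
  set.seed(seed)
  D <- array(runif(N * M * T), dim = c(N, M, T))
  cc <- matrix(rep(centre, each = T), T, 2)
  new("LogPolarSequence", data = D, centres = cc, rInit = 50)
}

# random non-negative edge cost maps for both contours
randomEdgeMaps <- function(N, M, T, seed = 2) {
  set.seed(seed)
  list(inner = array(runif(N * M * T), dim = c(N, M, T)),
       outer = array(runif(N * M * T), dim = c(N, M, T)))
}

# parameters for tiny joint instances: beams wide open relative to M so
# the state space stays rich, small minimum wall
tinyParams <- function(M, seed = 3, minWall = 1, beamSpatial = 2,
                       beamTemporal = M, tES = 1) {
  set.seed(seed)
  th <- stats::setNames(runif(14, 0.2, 1.5), thetaNames())
  crfParameters(theta = th, tES = tES, epsRho = 1,
                beamTemporal = beamTemporal, beamSpatial = beamSpatial,
                minWall = minWall)
}

# uniform prior over all wall thicknesses
uniformPrior <- function(M) new("WallPrior", pmf = rep(1 / M, M),
                                floor = 1e-6)

# a miniature of the segmentation problem: noisy two-step radial profiles
# (blood / wall / background at the phantom's intensity levels), classifier-
# like edge cost maps peaked off the true edges, a prior fitted from the
# instance's truth, and the default weights -- every factor family active
tinyInstance <- function(seed, N = 3L, M = 5L, T = 2L) {
  set.seed(seed)
  innerEdge <- matrix(sample(1:2, N * T, TRUE), N, T)
  outerEdge <- innerEdge + matrix(sample(1:2, N * T, TRUE), N, T)
  lv <- c(blood = 0.9, wall = 0.2, bg = 0.55)
  D <- array(0, c(N, M, T))
  for (t in 1:T) for (n in 1:N) {
    row <- ifelse(0:(M - 1) < innerEdge[n, t], lv["blood"],
                  ifelse(0:(M - 1) < outerEdge[n, t], lv["wall"], lv["bg"]))
    D[n, , t] <- row + rnorm(M, 0, 0.035)
  }
  mkMap <- function(edge) {
    a <- array(0, c(N, M, T))
    for (t in 1:T) for (n in 1:N) {
      cost <- 1 - exp(-((0:(M - 1)) - edge[n, t])^2 / 2) +
        abs(rnorm(M, 0, 0.05))
      cost <- cost - min(cost)
      a[n, , t] <- cost / sum(cost)
    }
    a
  }
  truth <- RadialSegmentation(innerEdge, outerEdge, matrix(0, T, 2), M)
  list(lps = new("LogPolarSequence", data = D, centres = matrix(0, T, 2),
                 rInit = 50),
       maps = list(inner = mkMap(innerEdge), outer = mkMap(outerEdge)),
       prior = fitWallPrior(truth, M = M),
       params = crfParameters(tES = 1, epsRho = 1, beamSpatial = 2,
                              beamTemporal = min(25, M), minWall = 1),
       truth = truth)
}

# exact ring shortest path over one frame, one contour, spatial-only
# model: unary N x M (theta-weighted edge costs), spatial pairwise
# thSp * ((a - b)/M)^2 with |a - b| <= beam. Conditions on rho_0; ties ->
# smallest bin. Mirrors nothing from the compiled code path.
ringDPOracle <- function(unary, thSp, beam) {
  N <- nrow(unary); M <- ncol(unary)
  pair <- function(a, b) {
    if (abs(a - b) > beam) return(Inf)
    thSp * ((a - b) / M)^2
  }
  bestTotal <- Inf; bestPath <- NULL
  for (v in 0:(M - 1)) {
    C <- rep(Inf, M); C[v + 1] <- unary[1, v + 1]
    bp <- matrix(NA_integer_, N, M)
    for (n in 2:N) {
      Cn <- rep(Inf, M)
      for (b in 0:(M - 1)) {
        lo <- max(0, b - beam); hi <- min(M - 1, b + beam)
        cand <- C[(lo:hi) + 1] + thSp * (((lo:hi) - b) / M)^2
        i <- which.min(cand)
        Cn[b + 1] <- cand[i] + unary[n, b + 1]
        bp[n, b + 1] <- lo + i - 1L
      }
      C <- Cn
    }
    cand <- C + vapply(0:(M - 1), function(r) pair(v, r), 0)
    i <- which.min(cand)
    if (cand[i] < bestTotal - 1e-12) {
      bestTotal <- cand[i]
      path <- integer(N); path[N] <- i - 1L
      for (n in N:2) path[n - 1] <- bp[n, path[n] + 1]
      bestPath <- path
    }
  }
  list(bins = as.integer(bestPath), cost = bestTotal)
}

# exhaustive centre-track enumeration for short sequences: all integer
# offset tracks from c0 back to c0 with per-frame steps <= maxStep and
# offsets capped at maxDrift; returns the minimum summed alignment cost
enumerateTracksCost <- function(seq, c0, sigma, maxStep = 2L, maxDrift = 2L) {
  fr <- frames(seq)
  T <- length(fr)
  states <- lapply(0:(T - 1), function(t) {
    r <- min(maxStep * min(t, T - 1 - t), maxDrift)
    as.matrix(expand.grid(dx = -r:r, dy = -r:r))
  })
  trans <- vector("list", T - 1)
  for (t in 2:T) {
    st <- states[[t]]; sp <- states[[t - 1]]
    Cm <- matrix(Inf, nrow(sp), nrow(st))
    for (i in seq_len(nrow(sp))) for (j in seq_len(nrow(st))) {
      if (max(abs(st[j, ] - sp[i, ])) > maxStep) next
      Cm[i, j] <- pairwiseAlignmentCost(fr[[t]], fr[[t - 1]],
                                        c0 + unlist(st[j, ]),
                                        c0 + unlist(sp[i, ]), sigma)
    }
    trans[[t - 1]] <- Cm
  }
  # enumerate intermediate frames (1..T-2); endpoints are fixed at c0
  mids <- lapply(2:(T - 1), function(t) seq_len(nrow(states[[t]])))
  grid <- as.matrix(expand.grid(mids))
  total <- trans[[1]][1, grid[, 1]]
  if (T > 3)
    for (k in 2:(T - 2))
      total <- total + trans[[k]][cbind(grid[, k - 1], grid[, k])]
  total <- total + trans[[T - 1]][grid[, ncol(grid)], 1]
  min(total)
}

# summed alignment cost of an estimated track
trackCost <- function(seq, track, sigma) {
  fr <- frames(seq)
  cc <- centres(track)
  s <- 0
  for (t in 2:length(fr))
    s <- s + pairwiseAlignmentCost(fr[[t]], fr[[t - 1]], cc[t, ], cc[t - 1, ],
                                   sigma)
  s
}

# memoised phantom study shared by the end-to-end tests (trained once)
.studyCache <- new.env(parent = emptyenv())
getPhantomStudy <- function() {
  if (is.null(.studyCache$study))
    .studyCache$study <- runPhantomStudy(seed = 7L)
  .studyCache$study
}

# record inference outputs (with the parameters they were produced under)
# so constraint compliance can be audited across tests
recordSegmentation <- function(seg, params) {
  .studyCache$segs <- c(.studyCache$segs,
                        list(list(seg = seg, params = params)))
}
recordedSegmentations <- function() .studyCache$segs
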