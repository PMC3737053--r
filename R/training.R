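# Discriminative weight training: symmetric landmark error between
# inferred and annotated contours minimised with Powell's derivative-free
# direction-set method in log-parameter space.

# minimum distances from points to a closed polygon boundary (point-to-
# segment, the closing edge included)
.pointsToPolyDist <- function(pts, poly) {
  p1 <- poly
  p2 <- poly[c(2:nrow(poly), 1L), , drop = FALSE]
  ex <- p2[, 1] - p1[, 1]; ey <- p2[, 2] - p1[, 2]
  len2 <- pmax(ex^2 + ey^2, 1e-12)
  dmin <- rep(Inf, nrow(pts))
  for (s in seq_len(nrow(p1))) {
    tt <- ((pts[, 1] - p1[s, 1]) * ex[s] + (pts[, 2] - p1[s, 2]) * ey[s]) / len2[s]
    tt <- pmin(pmax(tt, 0), 1)
    dx <- pts[, 1] - (p1[s, 1] + tt * ex[s])
    dy <- pts[, 2] - (p1[s, 2] + tt * ey[s])
    dmin <- pmin(dmin, sqrt(dx^2 + dy^2))
  }
  dmin
}

#' One-sided landmark error between two contours
#'
#' Mean over the reference polygon's vertices of the shortest distance to
#' the target polygon's boundary, scaled to mm. Non-symmetric: swapping
#' the arguments generally changes the value.
#'
#' @param ref,target closed polygons as k x 2 (x, y) vertex matrices.
#' @param spacing mm per pixel (scalar; anisotropic spacing should be
#'   resolved before calling).
#' @return error in mm.
#' @export
landmarkError <- function(ref, target, spacing = 1) {
  ref <- as.matrix(ref); target <- as.matrix(target)
  if (nrow(ref) == 0 || nrow(target) == 0) stop("empty contour")
  mean(.pointsToPolyDist(ref, target)) * spacing
}

#' Symmetric landmark error
#'
#' Average of the two one-sided landmark errors. Used as the training
#' objective: minimising the one-sided error alone rewards jagged inferred
#' contours, which the symmetrised form suppresses.
#'
#' @inheritParams landmarkError
#' @param a,b closed polygons as k x 2 (x, y) vertex matrices.
#' @export
symmetricError <- function(a, b, spacing = 1) {
  (landmarkError(a, b, spacing) + landmarkError(b, a, spacing)) / 2
}

# mean symmetric landmark error (mm) of a segmentation against truth,
# averaged over frames and both contours
.segmentationError <- function(seg, truth, rInit, spacing = 1) {
  M <- seg@M
  T <- nFrames(seg)
  err <- 0
  for (t in 1:T) {
    cc <- centres(truth)[t, ]
    for (kind in c("inner", "outer")) {
      pb <- if (kind == "inner") innerBins(seg)[, t] else outerBins(seg)[, t]
      tb <- if (kind == "inner") innerBins(truth)[, t] else outerBins(truth)[, t]
      err <- err + symmetricError(
        radialToCartesian(tb, cc, M, rInit),
        radialToCartesian(pb, centres(seg)[t, ], M, rInit), spacing)
    }
  }
  err / (2 * T)
}

#' Training objective for a weight vector
#'
#' Sum over annotated sequences of the mean symmetric landmark error of the
#' inferred segmentation, plus the weak log-parameter regularizer
#' \code{lambda * sum(log(theta))}. Inference is treated as a black box:
#' only the inferred contours are consulted.
#'
#' @param thetaVec named non-negative weights.
#' @param problems list of lists with elements \code{lps}
#'   (\code{LogPolarSequence}), \code{truth} (\code{RadialSegmentation}) and
#'   \code{edgeMaps} (precomputed cost arrays).
#' @param params structural \code{\link{CrfParameters}} (its theta slot is
#'   replaced by \code{thetaVec}).
#' @param prior a \code{\link{WallPrior}}.
#' @param lambda regularization weight.
#' @param spacing mm per pixel.
#' @param nIterations propagation iterations per inference call.
#' @export
trainingObjective <- function(thetaVec, problems, params, prior,
                              lambda = 1e-3, spacing = 1, nIterations = 3L) {
  p <- params
  p@theta <- thetaVec[thetaNames()]
  err <- 0
  for (pr in problems) {
    seg <- runInference(pr$lps, p, prior = prior, edgeMaps = pr$edgeMaps,
                        nIterations = nIterations)
    err <- err + .segmentationError(seg, pr$truth, pr$lps@rInit, spacing)
  }
  err + lambda * sum(log(thetaVec))
}

#' Scale-matched initial weights
#'
#' Default starting point for weight training. The edge-classifier costs
#' are normalised to sum to one over each radial row, so their per-node
#' scale is ~1/M; starting their weights at M/4 puts the edge evidence on
#' the same footing as the continuity terms. The wall-thickness prior
#' contributes ~-log P per node (order 1), far above the other families,
#' so its weight starts at 0.1. All other weights start at 1. Training
#' refines the balance from there.
#'
#' @param M radial bin count of the log-polar space.
#' @return named weight vector over \code{\link{thetaNames}}.
#' @export
initialTheta <- function(M) {
  th <- stats::setNames(rep(1, 14), thetaNames())
  th[c("innerEdge", "outerEdge")] <- M / 4
  th["crossRatio"] <- 0.1
  th
}

# golden-section line search of f over [lo, hi]; returns c(xmin, fmin, evals)
.lineSearch <- function(f, lo, hi, tol = 0.05, maxEval = 12L) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- f(x1); f2 <- f(x2); ev <- 2L
  while (b - a > tol && ev < maxEval) {
    if (f1 <= f2) { b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- f(x1)
    } else { a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- f(x2) }
    ev <- ev + 1L
  }
  if (f1 <= f2) c(x1, f1, ev) else c(x2, f2, ev)
}

#' Fit CRF weights with Powell's method
#'
#' Minimises the training objective over log(theta) (positivity enforced by
#' the parameterisation) with Powell's direction-set method: cyclic
#' bidirectional line searches along a direction list, the list updated
#' with the net displacement after each improving cycle. Objective
#' evaluations are cached by parameter hash, only improving steps are
#' accepted, and the run stops at \code{maxEvals} objective evaluations or
#' when a full cycle yields no improvement.
#'
#' @inheritParams trainingObjective
#' @param theta0 initial weights (default \code{\link{initialTheta}};
#'   must be positive).
#' @param maxEvals budget of objective evaluations (clinical-scale fits budget
#'   is about 300; phantom fits converge far sooner).
#' @param stepScale initial half-width of each line search in log-space.
#' @param tol line-search resolution in log-space.
#' @return a list with \code{params} (fitted \code{CrfParameters}),
#'   \code{objective} (final value), \code{trace} (objective after each
#'   accepted improvement, starting with the initial value) and
#'   \code{evals} (number of objective evaluations).
#' @export
powellFit <- function(problems, params, prior, theta0 = NULL, lambda = 1e-3,
                      spacing = 1, maxEvals = 300L, stepScale = 1,
                      tol = 0.05, nIterations = 3L) {
  if (is.null(theta0)) theta0 <- initialTheta(nBins(problems[[1]]$lps))
  if (any(theta0 <= 0)) stop("theta0 must be positive elementwise")
  nd <- length(thetaNames())
  cache <- new.env(parent = emptyenv())
  evals <- 0L
  obj <- function(x) {   # x = log theta
    key <- paste(signif(x, 12), collapse = ",")
    hit <- get0(key, envir = cache, inherits = FALSE)
    if (!is.null(hit)) return(hit)
    v <- trainingObjective(stats::setNames(exp(x), thetaNames()),
                           problems, params, prior, lambda, spacing,
                           nIterations)
    evals <<- evals + 1L
    assign(key, v, envir = cache)
    v
  }
  x <- log(unname(theta0[thetaNames()]))
  f0 <- obj(x)
  if (!is.finite(f0)) stop("objective not finite at theta0")
  fx <- f0
  trace <- f0
  dirs <- diag(nd)
  repeat {
    x0 <- x; fStart <- fx
    bestDrop <- 0; bestDir <- 1L
    for (d in seq_len(nd)) {
      if (evals >= maxEvals - 1L) break
      u <- dirs[, d]
      ls <- .lineSearch(function(a) obj(x + a * u), -stepScale, stepScale,
                        tol = tol, maxEval = maxEvals - evals)
      if (ls[2] < fx - 1e-10) {
        drop <- fx - ls[2]
        x <- x + ls[1] * u
        fx <- ls[2]
        trace <- c(trace, fx)
        if (drop > bestDrop) { bestDrop <- drop; bestDir <- d }
      }
    }
    if (evals >= maxEvals || fStart - fx <= 1e-10) break
    disp <- x - x0
    if (sqrt(sum(disp^2)) > 1e-8) {   # replace best-drop direction
      dirs[, bestDir] <- dirs[, nd]
      dirs[, nd] <- disp / sqrt(sum(disp^2))
      if (evals < maxEvals - 1L) {
        ls <- .lineSearch(function(a) obj(x + a * dirs[, nd]),
                          -stepScale, stepScale, tol = tol,
                          maxEval = maxEvals - evals)
        if (ls[2] < fx - 1e-10) {
          x <- x + ls[1] * dirs[, nd]
          fx <- ls[2]
          trace <- c(trace, fx)
        }
      }
    }
  }
  out <- params
  out@theta <- stats::setNames(exp(x), thetaNames())
  list(params = out, objective = fx, trace = trace, evals = evals)
}
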