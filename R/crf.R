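# The CRF energy: pairwise and unary feature functions over radial
# variables and the empirical wall-thickness prior. All features are
# non-negative and couple at most two radial variables; smaller values mean
# better segmentations. The energy is the theta-weighted sum over cliques.

#' Names of the CRF feature families
#'
#' The ~14 weight dimensions: per contour kind, the edge-classifier unary,
#' spatial and temporal continuity, systolic motion and the two
#' wall-intensity coherence terms; plus the two cross (inner-outer)
#' families.
#' @return character vector of length 14.
#' @export
thetaNames <- function() {
  c(paste0(rep(c("inner", "outer"), each = 6),
           c("Edge", "Spatial", "Temporal", "Systole",
             "IntensityTemporal", "IntensitySpatial")),
    "crossRatio", "wallVariance")
}

#' Construct a CRF parameter set
#'
#' @param theta named non-negative weights (defaults to all ones over
#'   \code{\link{thetaNames}}).
#' @param tES end-systole frame index (default 8).
#' @param epsRho radial offset in bins for the wall-intensity features.
#' @param beamTemporal,beamSpatial beam bounds on radial change across time
#'   and angle (defaults 25 and 2).
#' @param minWall minimum wall thickness rho_out - rho_in in bins.
#' @param profile "york" (minWall 10, epsRho 2) or "thin-wall" (minWall 2,
#'   epsRho 1) presets; explicit arguments override the profile.
#' @param wallVariant divisor convention of the wall-variance feature.
#' @return a \code{\link{CrfParameters}} object.
#' @export
crfParameters <- function(theta = NULL, tES = 8, epsRho = NULL,
                          beamTemporal = 25, beamSpatial = 2, minWall = NULL,
                          profile = c("york", "thin-wall"),
                          wallVariant = c("literal", "count")) {
  profile <- match.arg(profile)
  wallVariant <- match.arg(wallVariant)
  if (is.null(epsRho)) epsRho <- if (profile == "york") 2 else 1
  if (is.null(minWall)) minWall <- if (profile == "york") 10 else 2
  if (is.null(theta)) theta <- stats::setNames(rep(1, 14), thetaNames())
  new("CrfParameters", theta = theta[thetaNames()], tES = tES,
      epsRho = epsRho, beamTemporal = beamTemporal,
      beamSpatial = beamSpatial, minWall = minWall,
      wallVariant = wallVariant)
}

#' Spatial continuity feature
#'
#' Penalises radial jumps between adjacent angles of one frame:
#' \code{((rho_a - rho_b)/M)^2}. Symmetric, zero iff equal; the 1/M^2
#' scaling keeps it on the order of the edge features.
#'
#' @param rhoA,rhoB log-radius bins.
#' @param M radial bin count.
#' @export
fSpatial <- function(rhoA, rhoB, M) ((rhoA - rhoB) / M)^2

#' Temporal continuity feature
#'
#' Same functional form as \code{\link{fSpatial}} applied to the same angle
#' across consecutive frames.
#' @inheritParams fSpatial
#' @export
fTemporal <- function(rhoA, rhoB, M) ((rhoA - rhoB) / M)^2

#' Systolic motion feature
#'
#' Binary penalty on contour growth during systole (t < tES) and shrinkage
#' during diastole (t >= tES).
#'
#' @param rhoT bin at frame t.
#' @param rhoPrev bin at frame t - 1.
#' @param t frame index (>= 1).
#' @param tES end-systole frame.
#' @return 0 or 1.
#' @export
fSystole <- function(rhoT, rhoPrev, t, tES) {
  if (t < tES) as.numeric(rhoPrev < rhoT) else as.numeric(rhoT < rhoPrev)
}

# clamp a bin index into 0..M-1
.clampBin <- function(rho, M) pmin(pmax(rho, 0L), M - 1L)

#' Temporal wall-intensity coherence feature
#'
#' Absolute difference of the wall intensity sampled at a fixed radial
#' offset from the contour in consecutive frames: just inside the outer
#' contour (offset -epsRho) or just outside the inner contour (+epsRho).
#' Sampling indices are clamped to the valid bin range.
#'
#' @param dT,dPrev log-polar rows d_n(t) and d_n(t-1).
#' @param rhoT,rhoPrev contour bins at t and t-1.
#' @param epsRho radial offset in bins.
#' @param kind "outer" samples inside the contour, "inner" outside.
#' @export
fWallIntensityTemporal <- function(dT, dPrev, rhoT, rhoPrev, epsRho,
                                   kind = c("outer", "inner")) {
  kind <- match.arg(kind)
  off <- if (kind == "outer") -epsRho else epsRho
  M <- length(dT)
  abs(dT[.clampBin(rhoT + off, M) + 1L] - dPrev[.clampBin(rhoPrev + off, M) + 1L])
}

#' Spatial wall-intensity coherence feature
#'
#' The "angular gradient" of the wall: absolute difference of the intensity
#' sampled at a fixed offset from the contour at two adjacent angles, both
#' read from row n of the same frame.
#'
#' @param d log-polar row d_n(t).
#' @param rhoN,rhoNm1 contour bins at angles n and n - 1.
#' @inheritParams fWallIntensityTemporal
#' @export
fWallIntensitySpatial <- function(d, rhoN, rhoNm1, epsRho,
                                  kind = c("outer", "inner")) {
  kind <- match.arg(kind)
  off <- if (kind == "outer") -epsRho else epsRho
  M <- length(d)
  abs(d[.clampBin(rhoN + off, M) + 1L] - d[.clampBin(rhoNm1 + off, M) + 1L])
}

#' Fit the wall-thickness prior from annotations
#'
#' Normalised histogram of the log-radial wall thickness
#' \code{rho_out - rho_in} over all angles, frames and sequences, floored
#' at \code{floor} and renormalised so every feasible thickness keeps
#' finite negative-log cost.
#'
#' @param truths a \code{\link{RadialSegmentation}} or list of them.
#' @param floor minimum probability mass (default 1e-6).
#' @param M bin count (taken from the annotations when NULL).
#' @return a \code{\link{WallPrior}}.
#' @export
fitWallPrior <- function(truths, floor = 1e-6, M = NULL) {
  if (!is.list(truths)) truths <- list(truths)
  if (is.null(M)) M <- truths[[1]]@M
  deltas <- unlist(lapply(truths, function(s) outerBins(s) - innerBins(s)))
  if (any(deltas < 0))
    stop("annotation has outer contour inside inner contour")
  counts <- tabulate(deltas + 1L, nbins = M)
  pmf <- counts / sum(counts)
  pmf <- pmax(pmf, floor)
  new("WallPrior", pmf = pmf / sum(pmf), floor = floor)
}

#' Wall-thickness prior feature
#'
#' \code{-log P(rho_out - rho_in)} under the fitted prior; finite because
#' the pmf is floored.
#'
#' @param rhoIn,rhoOut contour bins with \code{rhoOut >= rhoIn}.
#' @param prior a \code{\link{WallPrior}}.
#' @export
fCrossRatio <- function(rhoIn, rhoOut, prior) {
  if (any(rhoOut < rhoIn)) stop("outer bin must not lie inside the inner bin")
  -log(wallPmf(prior)[rhoOut - rhoIn + 1L])
}

#' Wall-intensity variance feature
#'
#' Homogeneity of the myocardium: intensity variance over the bins between
#' the contours. The sum runs inclusively from rho_in to rho_out; the
#' printed normalisation divides by the wall width W = rho_out - rho_in
#' ("literal", the default), while "count" divides by the number of
#' summands W + 1 (the conventional variance).
#'
#' @param rhoIn,rhoOut contour bins with \code{rhoOut > rhoIn}.
#' @param d log-polar row d_n(t).
#' @param variant divisor convention.
#' @export
fWallVariance <- function(rhoIn, rhoOut, d, variant = c("literal", "count")) {
  variant <- match.arg(variant)
  W <- rhoOut - rhoIn
  if (W <= 0) stop("wall width must be positive")
  den <- if (variant == "literal") W else W + 1
  seg <- d[(rhoIn:rhoOut) + 1L]
  mu <- sum(seg) / den
  sum((seg - mu)^2) / den
}

#' Check beam and wall constraints of a segmentation
#'
#' TRUE when every temporal change is within \code{beamTemporal}, every
#' angular change (including the circular seam) within \code{beamSpatial},
#' and the wall thickness at least \code{minWall} everywhere.
#'
#' @param seg a \code{\link{RadialSegmentation}}.
#' @param params a \code{\link{CrfParameters}}.
#' @export
satisfiesConstraints <- function(seg, params) {
  ok <- TRUE
  for (bins in list(innerBins(seg), outerBins(seg))) {
    if (ncol(bins) > 1)
      ok <- ok && all(abs(bins[, -1, drop = FALSE] -
                          bins[, -ncol(bins), drop = FALSE]) <=
                        params@beamTemporal)
    rot <- bins[c(2:nrow(bins), 1L), , drop = FALSE]
    ok <- ok && all(abs(bins - rot) <= params@beamSpatial)
  }
  ok && all(outerBins(seg) - innerBins(seg) >= params@minWall)
}

#' Total CRF energy of a segmentation
#'
#' The theta-weighted sum over all cliques: per-node edge costs for both
#' contours; circular angular pairs within each frame (spatial continuity
#' and spatial wall-intensity); temporal pairs per angle (temporal
#' continuity, systolic motion and temporal wall-intensity); and the
#' inner-outer pairs per node (wall-thickness prior and wall variance).
#'
#' @param seg a \code{\link{RadialSegmentation}}.
#' @param lps the \code{\link{LogPolarSequence}} observation.
#' @param params a \code{\link{CrfParameters}}.
#' @param edgeMaps list with N x M x T cost arrays \code{inner} and
#'   \code{outer} (from \code{\link{edgeCostMaps}}), or NULL to drop the
#'   edge terms.
#' @param prior a \code{\link{WallPrior}}, or NULL to drop the prior term.
#' @return the scalar energy.
#' @export
totalEnergy <- function(seg, lps, params, edgeMaps = NULL, prior = NULL) {
  D <- lpData(lps)
  N <- dim(D)[1]; M <- dim(D)[2]; T <- dim(D)[3]
  if (!identical(dim(innerBins(seg)), c(N, T)))
    stop("segmentation dimensions do not match the observation")
  th <- theta(params)
  E <- 0
  binsOf <- list(inner = innerBins(seg), outer = outerBins(seg))
  for (kind in c("inner", "outer")) {
    bins <- binsOf[[kind]]
    pfx <- kind
    for (t in 1:T) {
      d_t <- D[, , t]
      b <- bins[, t]
      if (!is.null(edgeMaps))
        E <- E + th[paste0(pfx, "Edge")] *
          sum(edgeMaps[[kind]][cbind(1:N, b + 1L, t)])
      for (n in 1:N) {
        nm1 <- if (n == 1) N else n - 1L
        E <- E + th[paste0(pfx, "Spatial")] * fSpatial(b[n], b[nm1], M) +
          th[paste0(pfx, "IntensitySpatial")] *
            fWallIntensitySpatial(d_t[n, ], b[n], b[nm1], params@epsRho, kind)
        if (t > 1) {
          E <- E + th[paste0(pfx, "Temporal")] *
            fTemporal(b[n], bins[n, t - 1], M) +
            th[paste0(pfx, "Systole")] *
              fSystole(b[n], bins[n, t - 1], t - 1, params@tES) +
            th[paste0(pfx, "IntensityTemporal")] *
              fWallIntensityTemporal(d_t[n, ], D[n, , t - 1], b[n],
                                     bins[n, t - 1], params@epsRho, kind)
        }
      }
    }
  }
  for (t in 1:T) for (n in 1:N) {
    ri <- binsOf$inner[n, t]; ro <- binsOf$outer[n, t]
    if (!is.null(prior))
      E <- E + th["crossRatio"] * fCrossRatio(ri, ro, prior)
    if (ro > ri)
      E <- E + th["wallVariance"] *
        fWallVariance(ri, ro, D[n, , t], params@wallVariant)
  }
  unname(E)
}
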