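# MAP inference: min-sum loopy belief propagation with the sequential
# schedule (R front end over the compiled core), plus the exhaustive
# enumeration oracle for tiny instances.

#' Normalize a min-sum message
#'
#' Subtracts the smallest value so the message minimum is exactly zero
#' (the min-sum equivalent of scaling a max-product message to peak 1);
#' prevents numerical drift over iterations and preserves the argmin set.
#'
#' @param msg numeric cost vector with at least one finite entry.
#' @export
normalizeMessage <- function(msg) {
  m <- min(msg)
  if (!is.finite(m)) stop("message has no finite entry (empty beam)")
  msg - m
}

.zeroMaps <- function(N, M, T) array(0, dim = c(N, M, T))

.resolveEdgeMaps <- function(lps, bank, edgeMaps, erosionWidth) {
  N <- nAngles(lps); M <- nBins(lps); T <- nFrames(lps)
  if (!is.null(edgeMaps)) return(edgeMaps)
  if (!is.null(bank))
    return(list(inner = edgeCostMaps(bank, lps, "inner", erosionWidth),
                outer = edgeCostMaps(bank, lps, "outer", erosionWidth)))
  list(inner = .zeroMaps(N, M, T), outer = .zeroMaps(N, M, T))
}

#' Segment a log-polar sequence with loopy belief propagation
#'
#' Runs min-sum belief propagation over the radial CRF with the sequential
#' schedule: per iteration the inner contour is swept in the angular
#' direction (n = 0..N-1 and back) within each frame and then in the
#' temporal direction (t = 0..T-1 and back) for each angle, messages being
#' normalized as they are sent; the outer contour is then swept the same
#' way taking the inner-to-outer cross messages into account, and
#' outer-to-inner messages flow back at the start of the next iteration.
#' Beam constraints restrict radial changes across angle and time and the
#' inner-outer gap to at least \code{minWall}. After the final iteration
#' each frame's contour is recovered by an exact ring optimization over the
#' node beliefs (conditioning on the n = 0 bin, ties to the smallest bin),
#' frames in temporal order; the second contour is decoded against the
#' decided first one through the actual cross factor, so every output
#' satisfies the wall constraint. Both contour orders are decoded, each
#' followed by a block-coordinate refinement (exact re-solves of
#' frame-contour rings, rigid inner+outer pair moves and a global rigid
#' shift, every accepted move lowering the true energy), and the
#' lower-energy configuration is returned. The procedure is deterministic.
#'
#' @param lps a \code{\link{LogPolarSequence}} (already centred).
#' @param params a \code{\link{CrfParameters}}.
#' @param bank a trained \code{\link{EdgeClassifierBank}}, or NULL when
#'   \code{edgeMaps} are supplied directly.
#' @param prior a \code{\link{WallPrior}}, or NULL to drop the prior term.
#' @param edgeMaps optional precomputed list of N x M x T cost arrays
#'   \code{inner}/\code{outer}; passing these avoids recomputing classifier
#'   responses when only \code{theta} changes (as during training).
#' @param nIterations number of propagation iterations (default 3).
#' @param erosionWidth angular erosion width for computed edge maps.
#' @param contours which contours to infer; "both" (default) couples them
#'   through the cross factors.
#' @return a \code{\link{RadialSegmentation}}.
#' @export
runInference <- function(lps, params, bank = NULL, prior = NULL,
                         edgeMaps = NULL, nIterations = 3L,
                         erosionWidth = 3L,
                         contours = c("both", "inner", "outer")) {
  contours <- match.arg(contours)
  N <- nAngles(lps); M <- nBins(lps); T <- nFrames(lps)
  maps <- .resolveEdgeMaps(lps, bank, edgeMaps, erosionWidth)
  crossCost <- if (is.null(prior)) numeric(M) else -log(wallPmf(prior))
  if (contours == "both" && params@minWall > M - 1)
    stop("no state satisfies the minimum wall thickness; ",
         "consider the thin-wall profile")
  res <- .bp_segment(as.vector(lpData(lps)), as.integer(c(N, M, T)),
                     as.vector(maps$inner), as.vector(maps$outer),
                     unname(theta(params)[thetaNames()]),
                     as.integer(params@tES), as.integer(params@epsRho),
                     as.integer(params@beamTemporal),
                     as.integer(params@beamSpatial),
                     as.integer(params@minWall),
                     params@wallVariant == "literal",
                     crossCost, as.integer(nIterations),
                     switch(contours, both = 0L, inner = 1L, outer = 2L))
  inner <- res$inner; outer <- res$outer
  if (contours == "inner") outer <- pmin(inner + as.integer(params@minWall),
                                         M - 1L)
  if (contours == "outer") inner <- pmax(outer - as.integer(params@minWall), 0L)
  RadialSegmentation(inner, outer, centres(lps), M)
}

# pairwise cost tables for the enumeration oracle, built from the R-level
# feature functions (independent of the compiled BP feature evaluation)
.bruteTables <- function(lps, params, maps, prior) {
  D <- lpData(lps)
  N <- dim(D)[1]; M <- dim(D)[2]; T <- dim(D)[3]
  th <- theta(params)
  crossCost <- if (is.null(prior)) numeric(M) else -log(wallPmf(prior))
  big <- 1e15
  sp <- list(); tp <- list()
  for (kind in c("inner", "outer")) {
    spk <- array(0, c(M, M, N, T)); tpk <- array(0, c(M, M, N, T))
    off <- if (kind == "outer") -params@epsRho else params@epsRho
    base <- outer(0:(M - 1), 0:(M - 1), function(a, b) fSpatial(a, b, M))
    beamS <- outer(0:(M - 1), 0:(M - 1),
                   function(a, b) ifelse(abs(a - b) > params@beamSpatial, big, 0))
    beamT <- outer(0:(M - 1), 0:(M - 1),
                   function(a, b) ifelse(abs(a - b) > params@beamTemporal, big, 0))
    for (t in 1:T) for (n in 1:N) {
      dOff <- D[n, .clampBin(0:(M - 1) + off, M) + 1L, t]
      spk[, , n, t] <- th[paste0(kind, "Spatial")] * base +
        th[paste0(kind, "IntensitySpatial")] * abs(outer(dOff, dOff, "-")) +
        beamS
      if (t > 1) {
        dPrev <- D[n, .clampBin(0:(M - 1) + off, M) + 1L, t - 1]
        sys <- if ((t - 1) < params@tES)
          outer(0:(M - 1), 0:(M - 1), function(a, b) (b < a) + 0) else
          outer(0:(M - 1), 0:(M - 1), function(a, b) (a < b) + 0)
        tpk[, , n, t] <- th[paste0(kind, "Temporal")] * base +
          th[paste0(kind, "Systole")] * sys +
          th[paste0(kind, "IntensityTemporal")] *
            abs(outer(dOff, dPrev, "-")) + beamT
      }
    }
    sp[[kind]] <- spk; tp[[kind]] <- tpk
  }
  cross <- array(0, c(M, M, N, T))
  wv <- matrix(0, M, M)   # [ro, ri]
  for (t in 1:T) for (n in 1:N) {
    for (ri in 0:(M - 1)) for (ro in 0:(M - 1)) {
      wv[ro + 1, ri + 1] <- if (ro - ri < params@minWall) big else
        th["crossRatio"] * crossCost[ro - ri + 1] +
          (if (ro > ri) th["wallVariance"] *
             fWallVariance(ri, ro, D[n, , t], params@wallVariant) else 0)
    }
    cross[, , n, t] <- wv
  }
  un <- lapply(c(inner = "inner", outer = "outer"), function(kind) {
    u <- array(0, c(N, M, T))
    for (t in 1:T) u[, , t] <- th[paste0(kind, "Edge")] * maps[[kind]][, , t]
    u
  })
  list(unary = un, sp = sp, tp = tp, cross = cross)
}

#' Exact MAP segmentation by exhaustive enumeration
#'
#' Test oracle: enumerates every configuration satisfying the beam and
#' wall constraints and returns the global minimiser of
#' \code{\link{totalEnergy}} (pruned depth-first search; ties resolved to
#' the lexicographically smallest configuration). Only feasible for tiny
#' instances; the state-space size M^(2NT) must not exceed \code{cap}.
#'
#' @inheritParams runInference
#' @param cap maximum admissible number of configurations (default 3e8).
#' @param contours "both" or "inner" (single-contour enumeration).
#' @return a \code{\link{RadialSegmentation}} with attribute
#'   \code{"energy"} holding the constrained optimum (beam penalty terms
#'   excluded for feasible outputs).
#' @export
bruteForceSegment <- function(lps, params, prior = NULL, edgeMaps = NULL,
                              cap = 3e8, contours = c("both", "inner")) {
  contours <- match.arg(contours)
  N <- nAngles(lps); M <- nBins(lps); T <- nFrames(lps)
  nv <- (if (contours == "both") 2 else 1) * N * T
  if (nv * log(M) > log(cap))
    stop("instance above the enumeration cap")
  maps <- .resolveEdgeMaps(lps, NULL, edgeMaps, 3L)
  tb <- .bruteTables(lps, params, maps, prior)
  res <- .brute_force(as.integer(c(N, M, T)),
                      as.vector(tb$unary$inner), as.vector(tb$unary$outer),
                      as.vector(tb$sp$inner), as.vector(tb$sp$outer),
                      as.vector(tb$tp$inner), as.vector(tb$tp$outer),
                      as.vector(tb$cross), contours == "both")
  inner <- res$inner
  outer <- if (contours == "both") res$outer else
    pmin(inner + as.integer(params@minWall), M - 1L)
  seg <- RadialSegmentation(inner, outer, centres(lps), M)
  attr(seg, "energy") <- res$energy
  seg
}
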