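# Contour agreement metrics: Dice overlap on rasterized interiors, average
# perpendicular distance (APD), landmark error, good-contour percentage and
# per-frame/sequence summaries.

#' Dice overlap of two binary masks
#'
#' \code{2|A n B| / (|A| + |B|)}; 0 by convention when both masks are
#' empty. The Dice error is \code{1 - dice}.
#'
#' @param maskA,maskB logical matrices of identical dimensions.
#' @return overlap fraction in [0, 1].
#' @export
dice <- function(maskA, maskB) {
  if (!identical(dim(maskA), dim(maskB))) stop("mask shape mismatch")
  s <- sum(maskA) + sum(maskB)
  if (s == 0) return(0)
  2 * sum(maskA & maskB) / s
}

#' Rasterize a closed polygon to a pixel mask
#'
#' Even-odd membership of pixel centres (0-based integer coordinates)
#' inside the polygon.
#'
#' @param poly k x 2 (x, y) vertex matrix.
#' @param dim image dimensions c(rows, cols).
#' @return logical rows x cols matrix.
#' @export
rasterizeContour <- function(poly, dim) {
  x <- rep(0:(dim[2] - 1), each = dim[1])
  y <- rep(0:(dim[1] - 1), dim[2])
  bnd <- rbind(as.matrix(poly), as.matrix(poly)[1, ])
  inside <- mgcv::in.out(bnd, cbind(x, y))
  matrix(inside, dim[1], dim[2])
}

# resample a closed polygon to k points uniformly spaced along its perimeter
.resamplePolygon <- function(poly, k) {
  p <- rbind(as.matrix(poly), as.matrix(poly)[1, ])
  seglen <- sqrt(rowSums(diff(p)^2))
  cum <- c(0, cumsum(seglen))
  total <- cum[length(cum)]
  s <- seq(0, total, length.out = k + 1)[-(k + 1)]
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i <- pmin(i, nrow(p) - 1)
  f <- (s - cum[i]) / pmax(seglen[i], 1e-12)
  p[i, , drop = FALSE] + f * (p[i + 1, , drop = FALSE] - p[i, , drop = FALSE])
}

#' Average perpendicular distance between contours
#'
#' Mean distance from points densely resampled along the reference contour
#' to the target contour boundary, scaled to mm. Non-symmetric: the first
#' argument is the reference.
#'
#' @param ref,target closed polygons as k x 2 (x, y) vertex matrices.
#' @param spacing mm per pixel.
#' @param nSamples number of resampled reference points (default 512).
#' @return APD in mm.
#' @export
apd <- function(ref, target, spacing = 1, nSamples = 512L) {
  ref <- as.matrix(ref); target <- as.matrix(target)
  if (nrow(ref) == 0 || nrow(target) == 0) stop("empty contour")
  pts <- .resamplePolygon(ref, nSamples)
  mean(.pointsToPolyDist(pts, target)) * spacing
}

#' Evaluate a segmentation against ground truth
#'
#' Per frame and contour: Dice on rasterized interiors, APD, landmark
#' error and the good-contour flag (APD < 5 mm, the standard criterion).
#' Summaries per contour: mean and sd of Dice and APD, the geometric mean
#' of the Dice error over frames, and the good-contour percentage.
#'
#' @param pred,truth \code{\link{RadialSegmentation}} objects with equal
#'   frame counts.
#' @param spacing mm per pixel.
#' @param rInit reference radius of the bin scale.
#' @param imageDim image dimensions c(rows, cols) for rasterization; when
#'   NULL a bounding box covering both segmentations is used.
#' @param goodThreshold APD threshold in mm for a good contour.
#' @return list with \code{frames} (per-frame data frame) and
#'   \code{summary} (per-contour statistics).
#' @export
evaluateSequence <- function(pred, truth, spacing = 1, rInit = 50,
                             imageDim = NULL, goodThreshold = 5) {
  if (nFrames(pred) != nFrames(truth)) stop("frame-count mismatch")
  T <- nFrames(pred)
  M <- truth@M
  if (is.null(imageDim)) {
    ext <- ceiling(max(centres(pred), centres(truth)) +
                     binToRadius(M - 1, M, rInit)) + 2
    imageDim <- c(ext, ext)
  }
  rows <- list()
  for (t in 1:T) for (kind in c("inner", "outer")) {
    pb <- if (kind == "inner") innerBins(pred)[, t] else outerBins(pred)[, t]
    tb <- if (kind == "inner") innerBins(truth)[, t] else outerBins(truth)[, t]
    pPoly <- radialToCartesian(pb, centres(pred)[t, ], M, rInit)
    tPoly <- radialToCartesian(tb, centres(truth)[t, ], M, rInit)
    d <- dice(rasterizeContour(pPoly, imageDim),
              rasterizeContour(tPoly, imageDim))
    a <- apd(tPoly, pPoly, spacing)
    l <- landmarkError(tPoly, pPoly, spacing)
    rows[[length(rows) + 1]] <- data.frame(
      frame = t - 1L, contour = kind, dice = d, apd = a, landmark = l,
      good = a < goodThreshold)
  }
  perFrame <- do.call(rbind, rows)
  summarise <- function(df) {
    err <- pmax(1 - df$dice, 1e-12)
    data.frame(contour = df$contour[1],
               meanDice = mean(df$dice), sdDice = stats::sd(df$dice),
               meanApd = mean(df$apd), sdApd = stats::sd(df$apd),
               meanLandmark = mean(df$landmark),
               geomMeanDiceError = exp(mean(log(err))),
               goodPct = 100 * mean(df$good))
  }
  summary <- do.call(rbind, lapply(split(perFrame, perFrame$contour),
                                   summarise))
  rownames(summary) <- NULL
  list(frames = perFrame, summary = summary)
}
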