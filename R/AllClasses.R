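#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib lvcrf, .registration = TRUE
NULL

#' Cine sequence of grayscale frames
#'
#' Container for a short-axis cine acquisition covering one cardiac cycle:
#' \code{T} grayscale frames of identical size plus the pixel spacing in mm.
#' Frame 0 is end-diastole (before contraction); end-systole occurs near the
#' middle of the sequence.
#'
#' @slot frames list of numeric matrices (rows = y, columns = x), one per
#'   time point, all with identical dimensions and finite intensities.
#' @slot pixelSpacing numeric(2), mm per pixel in (x, y).
#' @export
setClass("CineSequence",
  representation(frames = "list", pixelSpacing = "numeric"))

setValidity("CineSequence", function(object) {
  if (length(object@frames) < 2L)
    return("a cine sequence needs at least 2 frames")
  dims <- vapply(object@frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    return("all frames must share identical dimensions")
  if (!all(vapply(object@frames, function(f) all(is.finite(f)), logical(1))))
    return("frame intensities must be finite")
  if (length(object@pixelSpacing) != 2L || any(object@pixelSpacing <= 0))
    return("pixelSpacing must be two positive values (mm/px in x and y)")
  TRUE
})

#' @rdname CineSequence-class
#' @param frames list of numeric matrices.
#' @param pixelSpacing mm per pixel in (x, y).
#' @export
CineSequence <- function(frames, pixelSpacing = c(1, 1)) {
  new("CineSequence", frames = lapply(frames, function(f) {
    storage.mode(f) <- "double"; f
  }), pixelSpacing = as.numeric(pixelSpacing))
}

#' Log-polar transformed sequence
#'
#' Per-frame log-polar images \code{D(t)}: row \code{n} of each N x M slice
#' holds the radial intensity profile \code{d_n(t)} along angle
#' \code{2*pi*n/N}, sampled at log-radius bins produced by
#' \code{\link{binToRadius}}. The per-frame centres used for the transform
#' are retained so radial contours can be mapped back to image coordinates.
#'
#' @slot data numeric array N x M x T.
#' @slot centres numeric T x 2 matrix of (x, y) centre points (0-based
#'   pixel-centre coordinates).
#' @slot rInit reference radius in pixels mapping to bin M/2.
#' @export
setClass("LogPolarSequence",
  representation(data = "array", centres = "matrix", rInit = "numeric"))

setValidity("LogPolarSequence", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L) return("data must be an N x M x T array")
  if (nrow(object@centres) != d[3] || ncol(object@centres) != 2L)
    return("centres must be a T x 2 matrix")
  if (object@rInit <= 1) return("rInit must exceed 1 pixel")
  TRUE
})

#' Radial segmentation of a cine sequence
#'
#' Inner (endocardial) and outer (epicardial) contours of every frame as
#' integer log-radius bins over N angles, plus the per-frame centre points
#' the bins are relative to.
#'
#' @slot inner integer N x T matrix of inner-contour bins.
#' @slot outer integer N x T matrix of outer-contour bins.
#' @slot centres numeric T x 2 matrix of (x, y) centres.
#' @slot M number of radial bins (bins lie in 0..M-1).
#' @export
setClass("RadialSegmentation",
  representation(inner = "matrix", outer = "matrix", centres = "matrix",
                 M = "numeric"))

setValidity("RadialSegmentation", function(object) {
  if (!identical(dim(object@inner), dim(object@outer)))
    return("inner and outer must have identical dimensions")
  if (nrow(object@centres) != ncol(object@inner))
    return("centres must have one row per frame")
  bins <- c(object@inner, object@outer)
  if (any(bins < 0) || any(bins > object@M - 1))
    return("bins must lie in 0..M-1")
  TRUE
})

#' @rdname RadialSegmentation-class
#' @param inner,outer integer N x T matrices of log-radius bins.
#' @param centres numeric T x 2 matrix.
#' @param M radial bin count.
#' @export
RadialSegmentation <- function(inner, outer, centres, M) {
  storage.mode(inner) <- "integer"
  storage.mode(outer) <- "integer"
  new("RadialSegmentation", inner = inner, outer = outer,
      centres = as.matrix(centres), M = as.numeric(M))
}

#' Centre-point track
#'
#' Per-frame ventricle centre points estimated by dynamic programming.
#' The track is periodic (last centre equals the first) and moves by less
#' than 3 px per coordinate between frames.
#'
#' @slot centres numeric T x 2 matrix of (x, y) centres.
#' @slot sigma Gaussian weight width (px) used for the alignment error.
#' @export
setClass("CentreTrack",
  representation(centres = "matrix", sigma = "numeric"))

setValidity("CentreTrack", function(object) {
  cc <- object@centres
  if (ncol(cc) != 2L || nrow(cc) < 2L) return("centres must be T x 2, T >= 2")
  if (any(abs(cc[nrow(cc), ] - cc[1, ]) > 1e-9))
    return("track must be periodic: centres[T-1] == centres[0]")
  if (any(abs(diff(cc)) >= 3))
    return("consecutive centres must differ by < 3 px per coordinate")
  if (object@sigma <= 0) return("sigma must be positive")
  TRUE
})

#' CRF weights and structural constants
#'
#' The non-negative feature weights theta plus the structural constants of
#' the model: the end-systole frame, the radial offset used by the
#' wall-intensity features, the spatial/temporal beam bounds and the minimum
#' wall thickness (in bins) enforced between the contours.
#'
#' @slot theta named non-negative numeric vector of feature-family weights.
#' @slot tES end-systole frame index.
#' @slot epsRho radial offset (bins) for wall-intensity sampling.
#' @slot beamTemporal maximum allowed |rho_n(t) - rho_n(t-1)|.
#' @slot beamSpatial maximum allowed |rho_n(t) - rho_{n-1}(t)|.
#' @slot minWall minimum allowed rho_out - rho_in (bins).
#' @slot wallVariant "literal" keeps the printed wall-variance divisor W;
#'   "count" divides by the number of summands W + 1.
#' @export
setClass("CrfParameters",
  representation(theta = "numeric", tES = "numeric", epsRho = "numeric",
                 beamTemporal = "numeric", beamSpatial = "numeric",
                 minWall = "numeric", wallVariant = "character"))

setValidity("CrfParameters", function(object) {
  if (is.null(names(object@theta)) || any(names(object@theta) == ""))
    return("theta must be a fully named vector")
  if (any(object@theta < 0)) return("theta must be non-negative elementwise")
  if (!setequal(names(object@theta), thetaNames()))
    return(paste("theta names must be exactly:",
                 paste(thetaNames(), collapse = ", ")))
  if (!object@wallVariant %in% c("literal", "count"))
    return("wallVariant must be 'literal' or 'count'")
  TRUE
})

#' Empirical wall-thickness prior
#'
#' Probability mass function of the log-radial wall thickness
#' \code{rho_out - rho_in}, fitted from annotations, floored so that unseen
#' thicknesses keep finite cost under the negative-log transform.
#'
#' @slot pmf numeric vector of probabilities over delta = 0..M-1, summing
#'   to 1.
#' @slot floor minimum mass given to any feasible delta before
#'   renormalization.
#' @export
setClass("WallPrior", representation(pmf = "numeric", floor = "numeric"))

setValidity("WallPrior", function(object) {
  if (abs(sum(object@pmf) - 1) > 1e-8) return("pmf must sum to 1")
  if (object@floor <= 0) return("floor must be positive")
  if (any(object@pmf <= 0)) return("pmf must be strictly positive (floored)")
  TRUE
})

#' Bank of direction-dependent edge classifiers
#'
#' 2 contour kinds x 8 angular groups of small feed-forward classifiers
#' (one hidden layer of two logistic units) scoring whether a radial window
#' is centred on a cardiac edge, plus the window and gradient settings that
#' feed them.
#'
#' @slot inner,outer lists of 8 fitted \code{nnet} classifiers (angular
#'   groups in order n = 0..15, 16..31, ...).
#' @slot windowWidth radial window width w (defaults to M/4).
#' @slot gradientThreshold epsilon of the binary gradient indicator
#'   (intensity units).
#' @slot edgeLabelDistance bins within which a window counts as an edge
#'   example during training.
#' @slot N,M angular/radial dimensions the bank was trained for.
#' @export
setClass("EdgeClassifierBank",
  representation(inner = "list", outer = "list", windowWidth = "numeric",
                 gradientThreshold = "numeric", edgeLabelDistance = "numeric",
                 N = "numeric", M = "numeric"))

setValidity("EdgeClassifierBank", function(object) {
  if (length(object@inner) != 8L || length(object@outer) != 8L)
    return("bank must hold 8 classifiers per contour kind")
  if (object@windowWidth < 2 || object@windowWidth > object@M)
    return("windowWidth must lie in [2, M]")
  TRUE
})

#' Synthetic cine phantom configuration
#'
#' Geometry, timing, intensity and noise settings of the synthetic
#' short-axis phantom: a bright blood pool that contracts to end-systole and
#' re-expands, a darker myocardial annulus, one-sided papillary-muscle-like
#' blobs adjacent to the endocardium, a smooth periodic centre drift and
#' additive Gaussian noise. Intensities are on a 0..1 scale.
#'
#' @slot imageSize image side length (px).
#' @slot T frame count for the cycle.
#' @slot tES end-systole frame (maximum contraction), ~T/2 by default.
#' @slot innerRadiusED end-diastolic inner (endocardial) radius, px.
#' @slot wallThickness end-diastolic wall thickness, px.
#' @slot contraction fractional reduction of the inner radius at
#'   end-systole, in (0, 1).
#' @slot blobCount,blobRadius papillary-muscle blob count and radius (px).
#' @slot blobAngles blob angular positions (degrees); defaults put all
#'   blobs on one side so direction-dependent classifiers see asymmetry.
#' @slot driftPerFrame maximum centre translation per frame (px, <= 2).
#' @slot levels named intensities: blood, wall, background.
#' @slot noiseSd additive Gaussian noise sd (intensity units).
#' @slot seed RNG seed used by \code{\link{generatePhantom}}.
#' @export
setClass("PhantomConfig",
  representation(imageSize = "numeric", T = "numeric", tES = "numeric",
                 innerRadiusED = "numeric", wallThickness = "numeric",
                 contraction = "numeric", blobCount = "numeric",
                 blobRadius = "numeric", blobAngles = "numeric",
                 driftPerFrame = "numeric", levels = "numeric",
                 noiseSd = "numeric", seed = "numeric"))

setValidity("PhantomConfig", function(object) {
  rES <- object@innerRadiusED * (1 - object@contraction)
  if (object@T < 2) return("need T >= 2 frames")
  if (object@tES <= 0 || object@tES >= object@T - 1)
    return("tES must lie strictly inside the cycle")
  if (object@contraction <= 0 || object@contraction >= 1)
    return("contraction must lie in (0, 1)")
  if (object@blobCount > 0 && rES <= object@blobRadius)
    return("end-systolic inner radius must exceed the blob radius")
  if (object@driftPerFrame > 2)
    return("centre drift must be <= 2 px per frame")
  if (!all(c("blood", "wall", "background") %in% names(object@levels)))
    return("levels must name blood, wall and background")
  outerED <- object@innerRadiusED + object@wallThickness
  if (outerED + 4 * object@driftPerFrame >= object@imageSize / 2)
    return("phantom geometry exceeds the image bounds")
  TRUE
})
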