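# Generics, accessors and show methods for the core containers.

#' Number of frames
#' @param x a sequence-like object.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Frame list of a cine sequence
#' @param x a \code{CineSequence}.
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' Per-frame centre points
#' @param x an object carrying a centre track.
#' @export
setGeneric("centres", function(x) standardGeneric("centres"))

#' Pixel spacing in mm
#' @param x a \code{CineSequence}.
#' @export
setGeneric("pixelSpacing", function(x) standardGeneric("pixelSpacing"))

#' Inner-contour bins
#' @param x a \code{RadialSegmentation}.
#' @export
setGeneric("innerBins", function(x) standardGeneric("innerBins"))

#' Outer-contour bins
#' @param x a \code{RadialSegmentation}.
#' @export
setGeneric("outerBins", function(x) standardGeneric("outerBins"))

#' @rdname nFrames
#' @export
setMethod("nFrames", "CineSequence", function(x) length(x@frames))
#' @rdname nFrames
#' @export
setMethod("nFrames", "LogPolarSequence", function(x) dim(x@data)[3])
#' @rdname nFrames
#' @export
setMethod("nFrames", "RadialSegmentation", function(x) ncol(x@inner))
#' @rdname nFrames
#' @export
setMethod("nFrames", "CentreTrack", function(x) nrow(x@centres))

#' @rdname frames
#' @export
setMethod("frames", "CineSequence", function(x) x@frames)
#' @rdname pixelSpacing
#' @export
setMethod("pixelSpacing", "CineSequence", function(x) x@pixelSpacing)

#' @rdname centres
#' @export
setMethod("centres", "LogPolarSequence", function(x) x@centres)
#' @rdname centres
#' @export
setMethod("centres", "RadialSegmentation", function(x) x@centres)
#' @rdname centres
#' @export
setMethod("centres", "CentreTrack", function(x) x@centres)

#' @rdname innerBins
#' @export
setMethod("innerBins", "RadialSegmentation", function(x) x@inner)
#' @rdname outerBins
#' @export
setMethod("outerBins", "RadialSegmentation", function(x) x@outer)

#' Log-polar data array
#'
#' @param x a \code{LogPolarSequence}.
#' @return the N x M x T array of log-polar intensities.
#' @export
lpData <- function(x) x@data

#' Number of angular directions of a log-polar sequence
#' @param x a \code{LogPolarSequence}.
#' @export
nAngles <- function(x) dim(x@data)[1]

#' Number of radial bins of a log-polar sequence
#' @param x a \code{LogPolarSequence} or \code{RadialSegmentation}.
#' @export
nBins <- function(x) if (is(x, "RadialSegmentation")) x@M else dim(x@data)[2]

#' Feature weights of a CRF parameter set
#' @param x a \code{CrfParameters}.
#' @export
theta <- function(x) x@theta

#' Wall-thickness probability mass function
#' @param x a \code{WallPrior}.
#' @export
wallPmf <- function(x) x@pmf

setMethod("show", "CineSequence", function(object) {
  d <- dim(object@frames[[1]])
  cat(sprintf("CineSequence: %d frames of %d x %d px, spacing %.3g x %.3g mm\n",
              length(object@frames), d[2], d[1],
              object@pixelSpacing[1], object@pixelSpacing[2]))
})

setMethod("show", "LogPolarSequence", function(object) {
  d <- dim(object@data)
  cat(sprintf("LogPolarSequence: N=%d angles, M=%d bins, T=%d frames, rInit=%g px\n",
              d[1], d[2], d[3], object@rInit))
})

setMethod("show", "RadialSegmentation", function(object) {
  cat(sprintf("RadialSegmentation: N=%d angles, T=%d frames, M=%g bins\n",
              nrow(object@inner), ncol(object@inner), object@M))
  cat(sprintf("  inner bins: %d..%d; outer bins: %d..%d\n",
              min(object@inner), max(object@inner),
              min(object@outer), max(object@outer)))
})

setMethod("show", "CentreTrack", function(object) {
  cat(sprintf("CentreTrack: %d frames, sigma=%g px\n",
              nrow(object@centres), object@sigma))
})

setMethod("show", "CrfParameters", function(object) {
  cat(sprintf(
    "CrfParameters: %d weights, tES=%g, epsRho=%g, beams (t=%g, s=%g), minWall=%g\n",
    length(object@theta), object@tES, object@epsRho,
    object@beamTemporal, object@beamSpatial, object@minWall))
})

setMethod("show", "WallPrior", function(object) {
  cat(sprintf("WallPrior over %d thickness bins (floor %g), mode at delta=%d\n",
              length(object@pmf), object@floor, which.max(object@pmf) - 1L))
})

setMethod("show", "EdgeClassifierBank", function(object) {
  cat(sprintf(
    "EdgeClassifierBank: 2 x 8 classifiers, w=%g, eps=%g, N=%g, M=%g\n",
    object@windowWidth, object@gradientThreshold, object@N, object@M))
})

setMethod("show", "PhantomConfig", function(object) {
  cat(sprintf(
    "PhantomConfig: %g px image, T=%g (tES=%g), r_in(ED)=%g px, wall=%g px, noise sd=%g\n",
    object@imageSize, object@T, object@tES, object@innerRadiusED,
    object@wallThickness, object@noiseSd))
})
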