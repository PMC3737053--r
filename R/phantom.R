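# Synthetic short-axis cine phantom: a bright blood pool contracting to
# end-systole inside a darker myocardial annulus, one-sided papillary
# blobs, smooth periodic centre drift, additive noise and exact ground
# truth. Discs are rasterized with a 1 px anti-aliasing ramp so edge
# gradients are finite and classifiers see realistic boundary profiles.

#' Construct a phantom configuration
#'
#' Defaults describe a mid-ventricular short-axis acquisition scaled to a
#' compact image: one cycle of 12 frames with end-systole in the middle, a
#' 24 px end-diastolic endocardial radius contracting by 35%, an 8 px wall,
#' two papillary blobs on one side of the blood pool, 1 px/frame centre
#' drift and additive noise at 5% of the blood-wall contrast. Intensities
#' are on a 0..1 scale with a bright blood pool, dark wall and intermediate
#' background.
#'
#' @param imageSize image side length in px.
#' @param T number of frames.
#' @param tES end-systole frame (defaults to T/2).
#' @param innerRadiusED end-diastolic inner radius in px.
#' @param wallThickness end-diastolic wall thickness in px.
#' @param contraction fractional inner-radius reduction at end-systole.
#' @param blobCount,blobRadius,blobAngles papillary blob count, radius (px)
#'   and angular positions (degrees, one-sided by default).
#' @param driftPerFrame maximum centre translation per frame in px.
#' @param levels named intensity levels (blood, wall, background).
#' @param noiseSd additive Gaussian noise standard deviation.
#' @param seed RNG seed.
#' @param preset "default", or "hypertrophy" for a thick-walled ventricle
#'   whose blood pool nearly vanishes at end-systole (the known failure
#'   mode of edge-driven segmentation).
#' @return a \code{\link{PhantomConfig}}.
#' @export
phantomConfig <- function(imageSize = 96, T = 12, tES = NULL,
                          innerRadiusED = 24, wallThickness = 8,
                          contraction = 0.35, blobCount = 2,
                          blobRadius = 3.5, blobAngles = c(-40, 25),
                          driftPerFrame = 1,
                          levels = c(blood = 0.9, wall = 0.2,
                                     background = 0.55),
                          noiseSd = 0.035, seed = 1,
                          preset = c("default", "hypertrophy")) {
  preset <- match.arg(preset)
  if (preset == "hypertrophy") {
    innerRadiusED <- 14; wallThickness <- 18; contraction <- 0.72
    blobCount <- 0
  }
  if (is.null(tES)) tES <- floor(T / 2)
  new("PhantomConfig", imageSize = imageSize, T = T, tES = tES,
      innerRadiusED = innerRadiusED, wallThickness = wallThickness,
      contraction = contraction, blobCount = blobCount,
      blobRadius = blobRadius,
      blobAngles = blobAngles[seq_len(max(blobCount, 1))],
      driftPerFrame = driftPerFrame, levels = levels, noiseSd = noiseSd,
      seed = seed)
}

# smooth strictly-unimodal inner radius: linear contraction to tES,
# linear re-expansion after
.innerRadius <- function(cfg, t) {
  rED <- cfg@innerRadiusED
  rES <- rED * (1 - cfg@contraction)
  if (t <= cfg@tES) rED + (rES - rED) * t / cfg@tES
  else rES + (rED - rES) * (t - cfg@tES) / (cfg@T - 1 - cfg@tES)
}

# the outer boundary contracts about a third as much as the inner one
.outerRadius <- function(cfg, t) {
  rOutED <- cfg@innerRadiusED + cfg@wallThickness
  rOutED - 0.3 * (cfg@innerRadiusED - .innerRadius(cfg, t))
}

.phantomCentre <- function(cfg, t) {
  amp <- cfg@driftPerFrame * (cfg@T - 1) / (2 * pi)
  mid <- (cfg@imageSize - 1) / 2
  ph <- 2 * pi * t / (cfg@T - 1)
  c(mid + amp * sin(ph), mid + amp * (1 - cos(ph)) / 2)
}

# signed-distance anti-aliased disc coverage at pixel grid
.discCoverage <- function(size, centre, radius) {
  x <- matrix(rep(0:(size - 1), each = size), size, size)  # col index = x
  y <- matrix(rep(0:(size - 1), size), size, size)         # row index = y
  d <- sqrt((x - centre[1])^2 + (y - centre[2])^2)
  pmin(pmax(radius - d + 0.5, 0), 1)
}

#' Generate a synthetic cine phantom with ground truth
#'
#' Renders one cardiac cycle: per frame a bright blood disc of radius
#' r_in(t) (strictly decreasing before end-systole, strictly increasing
#' after), a darker annular wall out to r_out(t), intermediate background,
#' dark papillary-muscle blobs placed on one side of the blood pool against
#' the endocardial border, a smooth periodic centre drift and additive
#' Gaussian noise. Ground truth holds the exact contours (as log-radius
#' bins around the drifting centres) and the centre track.
#'
#' @param cfg a \code{\link{PhantomConfig}}.
#' @param N,M log-polar resolution of the ground-truth bins.
#' @param rInit reference radius for the bin scale (defaults to the
#'   end-diastolic inner radius so truth sits near bin M/2 at
#'   end-diastole).
#' @return list with \code{seq} (\code{CineSequence}), \code{truth}
#'   (\code{RadialSegmentation}), \code{centres} (\code{CentreTrack}) and
#'   \code{blobs} (per-frame list of blob centre/radius matrices).
#' @export
generatePhantom <- function(cfg, N = 64L, M = 128L, rInit = NULL) {
  if (is.null(rInit)) rInit <- cfg@innerRadiusED
  set.seed(as.integer(cfg@seed))
  size <- cfg@imageSize
  T <- cfg@T
  lv <- cfg@levels
  framesL <- vector("list", T)
  inner <- matrix(0L, N, T); outer <- matrix(0L, N, T)
  cc <- matrix(0, T, 2, dimnames = list(NULL, c("x", "y")))
  blobs <- vector("list", T)
  for (t in 0:(T - 1)) {
    ctr <- .phantomCentre(cfg, t)
    rIn <- .innerRadius(cfg, t); rOut <- .outerRadius(cfg, t)
    img <- matrix(lv["background"], size, size)
    covOut <- .discCoverage(size, ctr, rOut)
    covIn <- .discCoverage(size, ctr, rIn)
    img <- img + (lv["wall"] - lv["background"]) * covOut +
      (lv["blood"] - lv["wall"]) * covIn
    bl <- NULL
    if (cfg@blobCount > 0) {
      ang <- cfg@blobAngles[seq_len(cfg@blobCount)] * pi / 180
      for (a in ang) {
        bc <- ctr + (rIn - cfg@blobRadius - 1) * c(cos(a), sin(a))
        covB <- .discCoverage(size, bc, cfg@blobRadius)
        img <- img + (lv["wall"] - lv["blood"]) * covB * covIn
        bl <- rbind(bl, c(bc, cfg@blobRadius))
      }
    }
    if (cfg@noiseSd > 0)
      img <- img + matrix(stats::rnorm(size * size, 0, cfg@noiseSd),
                          size, size)
    framesL[[t + 1]] <- img
    cc[t + 1, ] <- ctr
    inner[, t + 1] <- radiusToBin(rep(rIn, N), M, rInit)
    outer[, t + 1] <- radiusToBin(rep(rOut, N), M, rInit)
    blobs[[t + 1]] <- bl
  }
  list(seq = CineSequence(framesL),
       truth = RadialSegmentation(inner, outer, cc, M),
       centres = new("CentreTrack", centres = cc,
                     sigma = 0.5 * cfg@innerRadiusED),
       blobs = blobs)
}
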