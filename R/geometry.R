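# Log-polar contour geometry: log-radius discretisation, the log-polar
# transform and conversions between Cartesian polygons and radial contours.
#
# Conventions: 0-based pixel-centre coordinates with x along columns and y
# along rows; angles counter-clockwise from the +x axis, angle n covering
# 2*pi*n/N; natural logarithms throughout.

#' Map a radius in pixels to a log-radius bin
#'
#' Discretises a radius into one of M log-spaced bins,
#' \code{floor((M/2) * log(r) / log(rInit))}, clamped to 0..M-1. The
#' reference radius \code{rInit} maps to bin M/2, so a contour near its
#' end-diastolic size sits mid-scale, and smaller radii receive finer
#' resolution.
#'
#' @param r radius in pixels, >= 1 (radii below one pixel are not
#'   representable).
#' @param M number of radial bins.
#' @param rInit reference radius in pixels (> 1).
#' @return integer bin(s) in 0..M-1; vectorised over \code{r}.
#' @examples
#' radiusToBin(50, 256, 50)   # 128
#' radiusToBin(1, 256, 50)    # 0
#' @export
radiusToBin <- function(r, M = 256L, rInit = 50) {
  if (any(r < 1)) stop("radii below 1 px are not representable")
  if (M < 2) stop("M must be >= 2")
  if (rInit <= 1) stop("rInit must exceed 1")
  # guard: exact bin boundaries (e.g. the binToRadius roundtrip) must not
  # fall below themselves through floating-point floor
  b <- floor((M / 2) * log(r) / log(rInit) + 1e-9)
  as.integer(pmin(pmax(b, 0), M - 1))
}

#' Map a log-radius bin back to a radius in pixels
#'
#' Inverse of \code{\link{radiusToBin}} at bin resolution:
#' \code{exp(rho * 2 * log(rInit) / M)}. Satisfies
#' \code{radiusToBin(binToRadius(rho)) == rho} for every valid bin.
#'
#' @param rho integer bin(s) in 0..M-1.
#' @inheritParams radiusToBin
#' @return radius in pixels; vectorised over \code{rho}.
#' @export
binToRadius <- function(rho, M = 256L, rInit = 50) {
  if (any(rho < 0) || any(rho > M - 1)) stop("bin out of range 0..M-1")
  exp(rho * 2 * log(rInit) / M)
}

# bilinear sample of a matrix at 0-based (x, y); outside -> fill
.bilinear <- function(frame, x, y, fill = 0) {
  h <- nrow(frame); w <- ncol(frame)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  val <- function(xi, yi) {
    inb <- xi >= 0 & xi <= w - 1 & yi >= 0 & yi <= h - 1
    v <- rep(fill, length(xi))
    v[inb] <- frame[cbind(yi[inb] + 1L, xi[inb] + 1L)]
    v
  }
  v00 <- val(x0, y0); v10 <- val(x0 + 1, y0)
  v01 <- val(x0, y0 + 1); v11 <- val(x0 + 1, y0 + 1)
  (v00 * (1 - fx) + v10 * fx) * (1 - fy) + (v01 * (1 - fx) + v11 * fx) * fy
}

#' Log-polar transform of a single frame
#'
#' Resamples a frame onto (angle, log-radius) coordinates around a centre
#' point: output row \code{n}, column \code{rho} bilinearly interpolates the
#' source at \code{centre + binToRadius(rho) * (cos(2*pi*n/N), sin(2*pi*n/N))}.
#' Samples outside the image take the fill value 0.
#'
#' @param frame numeric matrix (rows = y, columns = x).
#' @param centre (x, y) centre in 0-based pixel coordinates; must lie
#'   inside the frame.
#' @param N number of angular directions.
#' @inheritParams radiusToBin
#' @return an N x M numeric matrix.
#' @export
logPolarTransform <- function(frame, centre, N = 128L, M = 256L, rInit = 50) {
  if (centre[1] < 0 || centre[1] > ncol(frame) - 1 ||
      centre[2] < 0 || centre[2] > nrow(frame) - 1)
    stop("centre lies outside the frame")
  ang <- 2 * pi * (seq_len(N) - 1L) / N
  rad <- binToRadius(0:(M - 1L), M, rInit)
  x <- centre[1] + outer(cos(ang), rad)           # N x M
  y <- centre[2] + outer(sin(ang), rad)
  matrix(.bilinear(frame, as.vector(x), as.vector(y)), nrow = N, ncol = M)
}

#' Log-polar transform of a whole sequence
#'
#' Applies \code{\link{logPolarTransform}} to every frame around its own
#' centre point, producing the observation space the CRF works in.
#'
#' @param seq a \code{\link{CineSequence}}.
#' @param centreTrack a \code{\link{CentreTrack}} or a T x 2 matrix of
#'   per-frame (x, y) centres.
#' @inheritParams logPolarTransform
#' @return a \code{\link{LogPolarSequence}}.
#' @export
logPolarSequence <- function(seq, centreTrack, N = 128L, M = 256L, rInit = 50) {
  cc <- if (is(centreTrack, "CentreTrack")) centres(centreTrack) else
    as.matrix(centreTrack)
  fr <- frames(seq)
  stopifnot(nrow(cc) == length(fr))
  D <- array(0, dim = c(N, M, length(fr)))
  for (t in seq_along(fr))
    D[, , t] <- logPolarTransform(fr[[t]], cc[t, ], N, M, rInit)
  new("LogPolarSequence", data = D, centres = cc, rInit = rInit)
}

#' Convert a Cartesian polygon to a radial contour
#'
#' Casts a ray from the centre at each of N uniformly spaced angles and
#' records the log-radius bin of the outermost intersection with the
#' polygon boundary. Using the outermost crossing makes the conversion
#' robust to slightly non-star-shaped annotations.
#'
#' @param polygon closed polygon as a k x 2 matrix of (x, y) vertices (the
#'   closing edge from the last vertex back to the first is implied).
#' @param centre (x, y) point strictly inside the polygon.
#' @inheritParams logPolarTransform
#' @return integer vector of N bins.
#' @export
contourToRadial <- function(polygon, centre, N = 128L, M = 256L, rInit = 50) {
  polygon <- as.matrix(polygon)
  p1 <- polygon
  p2 <- polygon[c(2:nrow(polygon), 1L), , drop = FALSE]
  ex <- p2[, 1] - p1[, 1]; ey <- p2[, 2] - p1[, 2]
  bins <- integer(N)
  for (n in seq_len(N)) {
    a <- 2 * pi * (n - 1L) / N
    dx <- cos(a); dy <- sin(a)
    # solve centre + t*d = p1 + s*e for each edge
    den <- dx * ey - dy * ex
    ok <- abs(den) > 1e-12
    qx <- p1[, 1] - centre[1]; qy <- p1[, 2] - centre[2]
    tt <- (qx * ey - qy * ex) / den
    ss <- (qx * dy - qy * dx) / den
    hit <- ok & tt > 0 & ss >= -1e-9 & ss < 1 - 1e-9
    if (!any(hit)) stop("ray misses the polygon; is the centre inside it?")
    bins[n] <- radiusToBin(max(tt[hit]), M, rInit)
  }
  bins
}

#' Convert a radial contour to a Cartesian polygon
#'
#' @param bins integer vector of N log-radius bins.
#' @param centre (x, y) centre point.
#' @inheritParams radiusToBin
#' @return an N x 2 matrix of (x, y) vertices (implicitly closed).
#' @export
radialToCartesian <- function(bins, centre, M = 256L, rInit = 50) {
  N <- length(bins)
  a <- 2 * pi * (seq_len(N) - 1L) / N
  r <- binToRadius(bins, M, rInit)
  cbind(x = centre[1] + r * cos(a), y = centre[2] + r * sin(a))
}
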