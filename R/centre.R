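# Centre-point tracking: Gaussian-weighted between-frame alignment error
# minimised by dynamic programming over integer pixel offsets with a beam
# constraint and periodic endpoints.

#' Gaussian centre weight
#'
#' Weight that locally enhances the alignment error around the current
#' centre point: \code{exp(-||c - p||^2 / sigma^2)}, truncated to exactly 0
#' beyond a 2*sigma radius where the contribution is negligible.
#'
#' @param cpt centre (x, y).
#' @param p pixel (x, y), or a k x 2 matrix of pixels.
#' @param sigma Gaussian width in pixels (> 0).
#' @return weight(s) in [0, 1].
#' @export
centreWeight <- function(cpt, p, sigma) {
  if (sigma <= 0) stop("sigma must be positive")
  p <- matrix(p, ncol = 2)
  d2 <- (p[, 1] - cpt[1])^2 + (p[, 2] - cpt[2])^2
  w <- exp(-d2 / sigma^2)
  w[d2 > (2 * sigma)^2] <- 0
  w
}

# integer offsets within the 2*sigma disc, with their weights
.weightDisc <- function(sigma) {
  r <- ceiling(2 * sigma)
  off <- as.matrix(expand.grid(dx = -r:r, dy = -r:r))
  d2 <- off[, 1]^2 + off[, 2]^2
  keep <- d2 <= (2 * sigma)^2
  list(off = off[keep, , drop = FALSE], w = exp(-d2[keep] / sigma^2))
}

# patch values of `frame` at centre+offsets (0-based coords); out of bounds -> 0
.patch <- function(frame, cpt, off) {
  x <- cpt[1] + off[, 1]; y <- cpt[2] + off[, 2]
  inb <- x >= 0 & x <= ncol(frame) - 1 & y >= 0 & y <= nrow(frame) - 1
  v <- numeric(nrow(off))
  v[inb] <- frame[cbind(y[inb] + 1L, x[inb] + 1L)]
  v
}

#' Weighted between-frame alignment cost
#'
#' Gaussian-weighted sum of squared intensity differences between the patch
#' around \code{cT} in the current frame and the patch around \code{cPrev}
#' in the previous frame. Pixels indexed outside either frame contribute
#' intensity 0; the sum is restricted to the 2*sigma disc around the
#' current centre.
#'
#' @param frameT,framePrev numeric matrices of identical shape.
#' @param cT,cPrev integer (x, y) centres (0-based).
#' @param sigma Gaussian width in pixels.
#' @return non-negative alignment cost.
#' @export
pairwiseAlignmentCost <- function(frameT, framePrev, cT, cPrev, sigma) {
  if (!identical(dim(frameT), dim(framePrev)))
    stop("frames must have identical shapes")
  disc <- .weightDisc(sigma)
  a <- .patch(frameT, cT, disc$off)
  b <- .patch(framePrev, cPrev, disc$off)
  sum(disc$w * (a - b)^2)
}

# translate a matrix by integer (dx, dy) with zero fill: S(x) = f(x - dx, y - dy)
.shiftImage <- function(f, dx, dy) {
  h <- nrow(f); w <- ncol(f)
  s <- matrix(0, h, w)
  xs <- max(1, 1 + dx):min(w, w + dx)
  ys <- max(1, 1 + dy):min(h, h + dy)
  if (length(xs) && length(ys))
    s[ys, xs] <- f[ys - dy, xs - dx, drop = FALSE]
  s
}

# weighted patch sums of `img` around each 0-based centre row of `cts`
.patchSums <- function(img, cts, disc) {
  h <- nrow(img); w <- ncol(img)
  nS <- nrow(cts); nD <- nrow(disc$off)
  x <- outer(cts[, 1], disc$off[, 1], "+")
  y <- outer(cts[, 2], disc$off[, 2], "+")
  inb <- x >= 0 & x <= w - 1 & y >= 0 & y <= h - 1
  v <- matrix(0, nS, nD)
  v[inb] <- img[cbind(y[inb] + 1L, x[inb] + 1L)]
  as.vector(v %*% disc$w)
}

#' Estimate per-frame centre points by dynamic programming
#'
#' Given the user-supplied centre of frame 0, finds the integer centre track
#' minimising the summed \code{\link{pairwiseAlignmentCost}} over consecutive
#' frames, subject to \code{centres[0] == centres[T-1] == c0} (the sequence
#' spans one periodic cardiac cycle) and a per-frame displacement of at most
#' \code{maxStep} pixels per coordinate. States other than \code{c0} are
#' infeasible at the endpoints; forward DP runs over the feasible offset
#' grid and backtracking starts at the final frame. Cost ties are broken by
#' the smallest lexicographic (dx, dy) frame-to-frame displacement.
#'
#' @param seq a \code{\link{CineSequence}}.
#' @param c0 user-supplied (x, y) centre of frame 0 (0-based pixels).
#' @param sigma Gaussian weight width in pixels.
#' @param maxStep maximum per-coordinate displacement between frames
#'   (default 2: the centre translates less than three pixels per frame).
#' @param maxDrift cap on the total offset from \code{c0} considered per
#'   coordinate (bounds the DP grid).
#' @return a \code{\link{CentreTrack}}.
#' @export
estimateCentres <- function(seq, c0, sigma, maxStep = 2L, maxDrift = 6L) {
  fr <- frames(seq)
  T <- length(fr)
  if (maxStep < 1) stop("maxStep must be >= 1")
  c0 <- round(as.numeric(c0))
  if (c0[1] < 0 || c0[1] > ncol(fr[[1]]) - 1 ||
      c0[2] < 0 || c0[2] > nrow(fr[[1]]) - 1)
    stop("c0 lies outside frame 0")
  if (T < 3) {
    cc <- matrix(rep(c0, each = T), ncol = 2,
                 dimnames = list(NULL, c("x", "y")))
    return(new("CentreTrack", centres = cc, sigma = sigma))
  }

  disc <- .weightDisc(sigma)
  # feasible per-coordinate offsets at frame t: reachable from c0 and able
  # to return to c0 by T-1, capped at maxDrift
  states <- lapply(0:(T - 1), function(t) {
    r <- min(maxStep * min(t, T - 1 - t), maxDrift)
    g <- as.matrix(expand.grid(dx = -r:r, dy = -r:r))
    g[order(g[, 1], g[, 2]), , drop = FALSE]
  })
  # frame-to-frame displacements in lexicographic (dx, dy) order, so the
  # first strict improvement realises the tie-break
  deltas <- as.matrix(expand.grid(dx = -maxStep:maxStep, dy = -maxStep:maxStep))
  deltas <- deltas[order(deltas[, 1], deltas[, 2]), , drop = FALSE]

  cost <- list(0)            # frame 0: only c0 feasible, cumulative cost 0
  back <- vector("list", T)
  for (t in 2:T) {
    st <- states[[t]]; sp <- states[[t - 1]]
    cts <- sweep(st, 2, c0, "+")
    spKey <- paste(sp[, 1], sp[, 2])
    ct <- rep(Inf, nrow(st)); bk <- rep(NA_integer_, nrow(st))
    for (k in seq_len(nrow(deltas))) {
      dlt <- deltas[k, ]
      j <- match(paste(st[, 1] - dlt[1], st[, 2] - dlt[2]), spKey)
      any_ok <- which(!is.na(j) & is.finite(cost[[t - 1]][j]))
      if (!length(any_ok)) next
      diffsq <- (fr[[t]] - .shiftImage(fr[[t - 1]], dlt[1], dlt[2]))^2
      v <- .patchSums(diffsq, cts[any_ok, , drop = FALSE], disc) +
        cost[[t - 1]][j[any_ok]]
      upd <- v < ct[any_ok] - 1e-12
      ct[any_ok[upd]] <- v[upd]
      bk[any_ok[upd]] <- j[any_ok][upd]
    }
    cost[[t]] <- ct; back[[t]] <- bk
  }

  endIdx <- which(states[[T]][, 1] == 0 & states[[T]][, 2] == 0)
  if (!is.finite(cost[[T]][endIdx])) stop("infeasible endpoint constraints")
  idx <- integer(T); idx[T] <- endIdx
  for (t in T:2) idx[t - 1] <- back[[t]][idx[t]]
  cc <- t(vapply(1:T, function(t) c0 + states[[t]][idx[t], ], numeric(2)))
  colnames(cc) <- c("x", "y")
  new("CentreTrack", centres = cc, sigma = sigma)
}
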