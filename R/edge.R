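# Learned edge costs: windowed gradient features, direction-dependent
# classifier training (2 contour kinds x 8 angular groups), cost transform,
# per-row normalization and angular erosion.

#' Extract a radial window from a log-polar row
#'
#' Returns the \code{w} intensities on \code{[rho - w/2, rho + w/2)};
#' positions outside 0..M-1 are edge-replicated. The window corresponds to
#' a circular sector of the original image.
#'
#' @param row length-M intensity vector.
#' @param rho centre bin (0-based).
#' @param w window width (even, <= M).
#' @return numeric vector of length \code{w}.
#' @export
extractWindow <- function(row, rho, w) {
  M <- length(row)
  if (w > M) stop("window width exceeds the row length")
  idx <- rho - w %/% 2 + 0:(w - 1)
  row[pmin(pmax(idx, 0L), M - 1L) + 1L]
}

#' Gradient feature vector of a radial window
#'
#' Concatenates four expressions of the radial gradient g (forward
#' differences of the window): g itself, |g|, sign(g) and the binary
#' indicator |g| > eps. Each block has length w - 1.
#'
#' @param v window of length w >= 2.
#' @param eps gradient threshold in intensity units.
#' @return numeric vector of length 4 * (w - 1).
#' @export
kappaFeature <- function(v, eps) {
  g <- diff(v)
  c(g, abs(g), sign(g), as.numeric(abs(g) > eps))
}

# angular group (0-based) serving angle n (0-based) out of N
.angleGroup <- function(n, N) n %/% (N %/% 8L)

# kappa features for every bin centre of one row: M x 4(w-1) matrix
.rowFeatures <- function(row, w, eps) {
  M <- length(row)
  idx <- outer(0:(M - 1), -(w %/% 2) + 0:(w - 1), "+")
  V <- matrix(row[pmin(pmax(idx, 0L), M - 1L) + 1L], M, w)
  G <- V[, 2:w, drop = FALSE] - V[, 1:(w - 1), drop = FALSE]
  cbind(G, abs(G), sign(G), (abs(G) > eps) + 0)
}

#' Train the bank of direction-dependent edge classifiers
#'
#' For each contour kind (inner/outer) and each of 8 groups of N/8
#' consecutive angles, trains a small feed-forward classifier (one hidden
#' layer of two logistic units, entropy fit) to separate edge windows from
#' non-edge windows. A window is an edge example when its centre is no more
#' than \code{edgeLabelDistance} bins from the ground-truth contour bin;
#' negatives are drawn uniformly from bins more than \code{farDistance}
#' bins away, one per positive, for class balance.
#'
#' @param lps list of \code{\link{LogPolarSequence}} objects.
#' @param truths list of matching \code{\link{RadialSegmentation}} ground
#'   truth annotations.
#' @param windowWidth radial window width (default M/4).
#' @param gradientThreshold eps of the gradient indicator; default 0.008,
#'   i.e. 2 intensity units on a 0-255 scale for images normalised to 0..1.
#' @param edgeLabelDistance bins within which a window is a positive
#'   example (default 2).
#' @param farDistance negatives are sampled beyond this distance (default 8).
#' @param seed RNG seed for sampling and network initialisation.
#' @param maxit training iterations per network.
#' @return an \code{\link{EdgeClassifierBank}}.
#' @export
trainEdgeClassifiers <- function(lps, truths, windowWidth = NULL,
                                 gradientThreshold = 0.008,
                                 edgeLabelDistance = 2L, farDistance = 8L,
                                 seed = 17L, maxit = 500L) {
  if (!is.list(lps)) lps <- list(lps)
  if (!is.list(truths)) truths <- list(truths)
  stopifnot(length(lps) >= 1, length(lps) == length(truths))
  N <- nAngles(lps[[1]]); M <- nBins(lps[[1]])
  if (is.null(windowWidth)) windowWidth <- M %/% 4L
  w <- as.integer(windowWidth)
  set.seed(as.integer(seed))

  gatherKind <- function(kind) {
    feats <- vector("list", 8L); labs <- vector("list", 8L)
    for (g in 1:8) { feats[[g]] <- list(); labs[[g]] <- list() }
    for (s in seq_along(lps)) {
      D <- lpData(lps[[s]])
      tr <- if (kind == "inner") innerBins(truths[[s]]) else
        outerBins(truths[[s]])
      for (t in seq_len(dim(D)[3])) {
        for (n in 0:(N - 1)) {
          row <- D[n + 1, , t]
          K <- .rowFeatures(row, w, gradientThreshold)
          rho <- tr[n + 1, t]
          pos <- (rho - edgeLabelDistance):(rho + edgeLabelDistance)
          pos <- pos[pos >= 0 & pos <= M - 1]
          far <- which(abs(0:(M - 1) - rho) > farDistance) - 1L
          if (length(far) == 0)
            stop("no non-edge windows beyond farDistance; reduce it")
          neg <- far[sample.int(length(far), length(pos),
                                replace = length(far) < length(pos))]
          g <- .angleGroup(n, N) + 1L
          feats[[g]] <- c(feats[[g]], list(K[c(pos, neg) + 1L, , drop = FALSE]))
          labs[[g]] <- c(labs[[g]],
                         list(rep(c(1, 0), c(length(pos), length(neg)))))
        }
      }
    }
    lapply(1:8, function(g) {
      X <- do.call(rbind, feats[[g]])
      y <- unlist(labs[[g]])
      if (length(unique(y)) < 2L)
        stop(sprintf("no %s examples of both classes in angular group %d",
                     kind, g - 1L))
      fit <- nnet::nnet(X, y, size = 2, entropy = TRUE, maxit = maxit,
                        decay = 1e-4, trace = FALSE, MaxNWts = 10000)
      .netWeights(fit, ncol(X))
    })
  }

  new("EdgeClassifierBank",
      inner = gatherKind("inner"), outer = gatherKind("outer"),
      windowWidth = w, gradientThreshold = gradientThreshold,
      edgeLabelDistance = as.numeric(edgeLabelDistance), N = N, M = M)
}

# extract the weight matrices of a fitted size-2 nnet: w1 is 2 x (p+1)
# (bias first), w2 is length 3 (bias, hidden1, hidden2)
.netWeights <- function(fit, p) {
  w <- fit$wts
  list(w1 = rbind(w[1:(p + 1)], w[(p + 2):(2 * (p + 1))]),
       w2 = w[(2 * (p + 1) + 1):(2 * (p + 1) + 3)])
}

# forward pass of the stored classifier over rows of X: logistic
# hidden/output activations, matching the trained network
.netPredict <- function(net, X) {
  Z <- stats::plogis(cbind(1, X) %*% t(net$w1))   # n x 2
  as.vector(stats::plogis(cbind(1, Z) %*% net$w2))
}

# circular minimum filter of width k along the first dimension (angles)
.angularErosion <- function(m, k) {
  if (k <= 1) return(m)
  h <- (k - 1) %/% 2
  out <- m
  for (s in setdiff(-h:h, 0L)) {
    shifted <- m[((seq_len(nrow(m)) - 1 + s) %% nrow(m)) + 1L, , drop = FALSE]
    out <- pmin(out, shifted)
  }
  out
}

#' Edge cost map of one log-polar frame
#'
#' Runs the trained classifiers over every (angle, bin) position of a
#' log-polar frame and converts responses to costs: cost = 1 - response,
#' then per radial row the row minimum is subtracted (no negative features)
#' and the row is normalised by its sum; rows that become identically zero
#' normalise to the uniform row 1/M. Finally a small circular minimum
#' filter (erosion) of width \code{erosionWidth} is applied in the angular
#' direction, so a position is penalised only if its angular neighbours
#' also respond as non-edges.
#'
#' @param bank a trained \code{\link{EdgeClassifierBank}}.
#' @param lpFrame N x M log-polar frame.
#' @param contourKind "inner" or "outer".
#' @param erosionWidth width of the angular minimum filter (default 3).
#' @return an N x M matrix of non-negative costs.
#' @export
edgeCostMap <- function(bank, lpFrame, contourKind = c("inner", "outer"),
                        erosionWidth = 3L) {
  contourKind <- match.arg(contourKind)
  nets <- slot(bank, contourKind)
  N <- nrow(lpFrame); M <- ncol(lpFrame)
  if (N != bank@N || M != bank@M)
    stop("frame dimensions do not match the trained bank")
  cost <- matrix(0, N, M)
  for (n in 0:(N - 1)) {
    K <- .rowFeatures(lpFrame[n + 1, ], bank@windowWidth,
                      bank@gradientThreshold)
    net <- nets[[.angleGroup(n, N) + 1L]]
    cost[n + 1, ] <- 1 - .netPredict(net, K)
  }
  cost <- cost - apply(cost, 1, min)
  rs <- rowSums(cost)
  zero <- rs <= 1e-12
  cost[!zero, ] <- cost[!zero, , drop = FALSE] / rs[!zero]
  cost[zero, ] <- 1 / M
  .angularErosion(cost, erosionWidth)
}

#' Edge cost maps for a whole sequence
#'
#' @inheritParams edgeCostMap
#' @param lps a \code{\link{LogPolarSequence}}.
#' @return an N x M x T array of costs.
#' @export
edgeCostMaps <- function(bank, lps, contourKind = c("inner", "outer"),
                         erosionWidth = 3L) {
  contourKind <- match.arg(contourKind)
  D <- lpData(lps)
  out <- array(0, dim = dim(D))
  for (t in seq_len(dim(D)[3]))
    out[, , t] <- edgeCostMap(bank, D[, , t], contourKind, erosionWidth)
  out
}
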