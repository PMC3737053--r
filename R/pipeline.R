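# End-to-end drivers: segment a cine sequence from a first-frame centre,
# and the self-contained phantom study (generate, train, fit, segment,
# evaluate) that exercises every stage of the method.

#' Segment a cine sequence
#'
#' The full inference path for one sequence: track centres from the
#' user-supplied first-frame centre, log-polar transform every frame
#' around its centre, and run belief propagation with the supplied
#' parameters, classifier bank and wall prior.
#'
#' @param seq a \code{\link{CineSequence}}.
#' @param c0 (x, y) centre of frame 0 (0-based pixels).
#' @param params a \code{\link{CrfParameters}}.
#' @param bank a trained \code{\link{EdgeClassifierBank}}.
#' @param prior a \code{\link{WallPrior}}.
#' @param N,M,rInit log-polar resolution and reference radius.
#' @param sigma centre-tracking Gaussian width (px).
#' @param nIterations propagation iterations.
#' @return list with \code{seg} (\code{RadialSegmentation}),
#'   \code{centres} (\code{CentreTrack}) and \code{lps}
#'   (\code{LogPolarSequence}).
#' @export
segmentCine <- function(seq, c0, params, bank, prior, N = 128L, M = 256L,
                        rInit = 50, sigma = 0.5 * rInit, nIterations = 3L) {
  track <- estimateCentres(seq, c0, sigma)
  lps <- logPolarSequence(seq, track, N, M, rInit)
  seg <- runInference(lps, params, bank = bank, prior = prior,
                      nIterations = nIterations)
  list(seg = seg, centres = track, lps = lps)
}

# fraction of papillary-blob area enclosed by the predicted inner contours
.blobContainment <- function(seg, blobs, imageDim, rInit) {
  tot <- 0; inside <- 0
  for (t in seq_len(nFrames(seg))) {
    bl <- blobs[[t]]
    if (is.null(bl)) next
    poly <- radialToCartesian(innerBins(seg)[, t], centres(seg)[t, ],
                              seg@M, rInit)
    mask <- rasterizeContour(poly, imageDim)
    for (b in seq_len(nrow(bl))) {
      cov <- .discCoverage(imageDim[1], bl[b, 1:2], bl[b, 3]) >= 0.5
      tot <- tot + sum(cov)
      inside <- inside + sum(cov & mask)
    }
  }
  if (tot == 0) return(NA_real_)
  inside / tot
}

#' Run the complete phantom study
#'
#' The package's canonical self-contained experiment: generates training
#' and held-out phantom sequences, trains the edge-classifier bank and the
#' wall prior on the training truth, fits the CRF weights with Powell's
#' method, segments the held-out phantoms through the full pipeline
#' (centre tracking from the true frame-0 centre, log-polar transform,
#' belief propagation) and evaluates against ground truth.
#'
#' @param cfg base \code{\link{PhantomConfig}}; each sequence gets its own
#'   seed derived from \code{seed}.
#' @param nTrain,nTest number of training / held-out sequences.
#' @param N,M log-polar resolution (defaults sized to the phantom).
#' @param seed master seed.
#' @param maxEvals Powell evaluation budget.
#' @param minWall minimum wall thickness in bins for the phantom scale.
#' @param lambda regularizer weight.
#' @param nIterations propagation iterations.
#' @return list with the trained \code{bank}, \code{prior}, \code{fit}
#'   (Powell result), per-sequence \code{tests} (segmentation, evaluation,
#'   blob containment) and the pooled \code{summary} data frame.
#' @export
runPhantomStudy <- function(cfg = phantomConfig(), nTrain = 3L, nTest = 3L,
                            N = 64L, M = 128L, seed = 1L, maxEvals = 100L,
                            minWall = 4L, lambda = 1e-3, nIterations = 3L) {
  rInit <- cfg@innerRadiusED
  # the CRF's tES marks the first frame treated as diastolic; the phantom's
  # end-systolic frame itself is reached by contraction, hence the +1
  params <- crfParameters(tES = cfg@tES + 1, minWall = minWall)
  mkPhantom <- function(i) {
    c2 <- cfg; c2@seed <- seed * 1000 + i
    generatePhantom(c2, N, M, rInit)
  }
  train <- lapply(seq_len(nTrain), mkPhantom)
  test <- lapply(nTrain + seq_len(nTest), mkPhantom)

  trainLps <- lapply(train, function(ph)
    logPolarSequence(ph$seq, ph$centres, N, M, rInit))
  bank <- trainEdgeClassifiers(trainLps, lapply(train, `[[`, "truth"),
                               seed = seed)
  prior <- fitWallPrior(lapply(train, `[[`, "truth"), M = M)

  problems <- lapply(seq_len(nTrain), function(i) list(
    lps = trainLps[[i]], truth = train[[i]]$truth,
    edgeMaps = list(
      inner = edgeCostMaps(bank, trainLps[[i]], "inner"),
      outer = edgeCostMaps(bank, trainLps[[i]], "outer"))))
  fit <- powellFit(problems, params, prior, lambda = lambda,
                   maxEvals = maxEvals, nIterations = nIterations)

  size <- cfg@imageSize
  tests <- lapply(test, function(ph) {
    c0 <- round(centres(ph$centres)[1, ])
    res <- segmentCine(ph$seq, c0, fit$params, bank, prior, N, M, rInit,
                       sigma = 0.5 * cfg@innerRadiusED,
                       nIterations = nIterations)
    ev <- evaluateSequence(res$seg, ph$truth, spacing = 1, rInit = rInit,
                           imageDim = c(size, size))
    list(seg = res$seg, centres = res$centres, truth = ph$truth,
         eval = ev,
         blobContainment = .blobContainment(res$seg, ph$blobs,
                                            c(size, size), rInit))
  })
  pooled <- do.call(rbind, lapply(tests, function(x) x$eval$frames))
  agg <- do.call(rbind, lapply(split(pooled, pooled$contour), function(df)
    data.frame(contour = df$contour[1], meanDice = mean(df$dice),
               meanApd = mean(df$apd), goodPct = 100 * mean(df$good))))
  rownames(agg) <- NULL
  list(bank = bank, prior = prior, fit = fit, params = fit$params,
       tests = tests, summary = agg)
}
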