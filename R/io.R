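# Reading and writing the external formats: frame stacks (PNG/TIFF
# directories, multi-frame TIFF, NIfTI), contour tables (CSV/JSON), centre
# tracks, classifier banks and parameter configs.

.toGray <- function(a) {
  if (length(dim(a)) == 3) a <- apply(a[, , 1:min(3, dim(a)[3]), drop = FALSE],
                                      c(1, 2), mean)
  a
}

#' Read a cine sequence from files
#'
#' Accepts a directory of ordered PNG/TIFF frames (alphabetical order =
#' temporal order), a single multi-frame TIFF, or a NIfTI stack (requires
#' the RNifti package); colour frames are averaged to grayscale.
#'
#' @param path directory or file path.
#' @param pixelSpacing mm per pixel (x, y); supplied by the caller, no
#'   DICOM metadata is read.
#' @return a \code{\link{CineSequence}}.
#' @export
readCineSequence <- function(path, pixelSpacing = c(1, 1)) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) < 2) stop("need at least two frame files")
    fr <- lapply(files, function(f) {
      if (grepl("\\.png$", f, ignore.case = TRUE))
        .toGray(png::readPNG(f))
      else .toGray(tiff::readTIFF(f))
    })
  } else if (grepl("\\.(tif|tiff)$", path, ignore.case = TRUE)) {
    fr <- tiff::readTIFF(path, all = TRUE)
    fr <- lapply(fr, .toGray)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("reading NIfTI requires the RNifti package")
    vol <- RNifti::asNifti(RNifti::readNifti(path))
    fr <- lapply(seq_len(dim(vol)[3]), function(t) t(vol[, , t]))
  } else stop("unrecognised frame input: ", path)
  CineSequence(fr, pixelSpacing)
}

#' Write frames of a cine sequence as PNG files
#'
#' @param seq a \code{\link{CineSequence}}.
#' @param dir output directory (created if missing).
#' @return the file paths, invisibly.
#' @export
writeCineSequence <- function(seq, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fr <- frames(seq)
  lo <- min(vapply(fr, min, 0)); hi <- max(vapply(fr, max, 0))
  paths <- character(length(fr))
  for (t in seq_along(fr)) {
    paths[t] <- file.path(dir, sprintf("frame_%03d.png", t - 1L))
    png::writePNG((fr[[t]] - lo) / max(hi - lo, 1e-12), paths[t])
  }
  invisible(paths)
}

#' Convert a radial segmentation to a contour table
#'
#' Long-format table (frame, kind, vertex_index, x, y) of the per-frame
#' inner/outer polygons, 0-based pixel coordinates.
#'
#' @param seg a \code{\link{RadialSegmentation}}.
#' @param rInit reference radius of the bin scale.
#' @return a data.frame.
#' @export
segmentationToTable <- function(seg, rInit = 50) {
  M <- seg@M
  rows <- list()
  for (t in 1:nFrames(seg)) for (kind in c("inner", "outer")) {
    b <- if (kind == "inner") innerBins(seg)[, t] else outerBins(seg)[, t]
    poly <- radialToCartesian(b, centres(seg)[t, ], M, rInit)
    rows[[length(rows) + 1]] <- data.frame(
      frame = t - 1L, kind = kind, vertex_index = seq_len(nrow(poly)) - 1L,
      x = poly[, 1], y = poly[, 2])
  }
  do.call(rbind, rows)
}

#' Write contours to CSV
#'
#' @inheritParams segmentationToTable
#' @param path output CSV path.
#' @export
writeContoursCSV <- function(seg, path, rInit = 50) {
  utils::write.csv(segmentationToTable(seg, rInit), path, row.names = FALSE)
  invisible(path)
}

#' Read annotation contours from CSV or JSON
#'
#' CSV columns: frame, kind ("inner"/"outer"), vertex_index, x, y. The
#' JSON schema is a list of \code{{frame, kind, vertices: [[x, y], ...]}}
#' records. Returns per-frame polygons.
#'
#' @param path input file.
#' @return nested list: \code{polys[[frame + 1]][[kind]]} is a k x 2
#'   matrix.
#' @export
readContours <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    rec <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
    df <- do.call(rbind, lapply(rec, function(r) {
      v <- if (is.list(r$vertices)) do.call(rbind, lapply(r$vertices, unlist))
           else matrix(r$vertices, ncol = 2)
      data.frame(frame = r$frame, kind = r$kind,
                 vertex_index = seq_len(nrow(v)) - 1L,
                 x = v[, 1], y = v[, 2])
    }))
  } else {
    df <- utils::read.csv(path)
  }
  frames <- sort(unique(df$frame))
  lapply(frames, function(fi) {
    out <- list()
    for (kind in unique(df$kind[df$frame == fi])) {
      sub <- df[df$frame == fi & df$kind == kind, ]
      sub <- sub[order(sub$vertex_index), ]
      out[[kind]] <- cbind(x = sub$x, y = sub$y)
    }
    out
  })
}

#' Convert annotation polygons to a radial segmentation
#'
#' @param polys nested list as returned by \code{\link{readContours}}.
#' @param centreTrack per-frame centres (\code{\link{CentreTrack}} or
#'   T x 2 matrix).
#' @inheritParams contourToRadial
#' @return a \code{\link{RadialSegmentation}}.
#' @export
contoursToSegmentation <- function(polys, centreTrack, N = 128L, M = 256L,
                                   rInit = 50) {
  cc <- if (is(centreTrack, "CentreTrack")) centres(centreTrack) else
    as.matrix(centreTrack)
  T <- length(polys)
  inner <- matrix(0L, N, T); outer <- matrix(0L, N, T)
  for (t in 1:T) {
    inner[, t] <- contourToRadial(polys[[t]]$inner, cc[t, ], N, M, rInit)
    outer[, t] <- contourToRadial(polys[[t]]$outer, cc[t, ], N, M, rInit)
  }
  RadialSegmentation(inner, outer, cc, M)
}

#' Write a centre track to CSV
#'
#' @param track a \code{\link{CentreTrack}}.
#' @param path output CSV path.
#' @export
writeCentresCSV <- function(track, path) {
  cc <- centres(track)
  utils::write.csv(data.frame(frame = seq_len(nrow(cc)) - 1L,
                              x = cc[, 1], y = cc[, 2]),
                   path, row.names = FALSE)
  invisible(path)
}

#' Save / load an edge classifier bank as JSON
#'
#' Stores the weight matrices and window settings of all 16 classifiers in
#' a single JSON archive.
#'
#' @param bank an \code{\link{EdgeClassifierBank}}.
#' @param path JSON file path.
#' @export
saveBank <- function(bank, path) {
  ser <- function(nets) lapply(nets, function(n)
    list(w1 = as.vector(n$w1), w2 = n$w2, p = ncol(n$w1) - 1L))
  jsonlite::write_json(list(
    inner = ser(bank@inner), outer = ser(bank@outer),
    windowWidth = bank@windowWidth,
    gradientThreshold = bank@gradientThreshold,
    edgeLabelDistance = bank@edgeLabelDistance,
    N = bank@N, M = bank@M), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveBank
#' @export
loadBank <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                          simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  des <- function(nets) lapply(nets, function(n)
    list(w1 = matrix(unlist(n$w1), nrow = 2), w2 = as.numeric(unlist(n$w2))))
  new("EdgeClassifierBank",
      inner = des(j$inner), outer = des(j$outer),
      windowWidth = j$windowWidth, gradientThreshold = j$gradientThreshold,
      edgeLabelDistance = j$edgeLabelDistance, N = j$N, M = j$M)
}

#' Read / write CRF parameters as a YAML or JSON config
#'
#' The config holds the theta vector and the structural constants (tES,
#' epsRho, beams, minWall, wall-variance variant).
#'
#' @param params a \code{\link{CrfParameters}}.
#' @param path file path ending in .yaml/.yml or .json.
#' @export
writeParams <- function(params, path) {
  obj <- list(theta = as.list(theta(params)), tES = params@tES,
              epsRho = params@epsRho, beamTemporal = params@beamTemporal,
              beamSpatial = params@beamSpatial, minWall = params@minWall,
              wallVariant = params@wallVariant)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::write_yaml(obj, path)
  else jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeParams
#' @export
readParams <- function(path) {
  j <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::fromJSON(path)
  crfParameters(theta = unlist(j$theta), tES = j$tES, epsRho = j$epsRho,
                beamTemporal = j$beamTemporal, beamSpatial = j$beamSpatial,
                minWall = j$minWall,
                wallVariant = j$wallVariant)
}
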