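#' Default per-tissue effective attenuation coefficients
#'
#' Effective attenuation (mm^-1) used by the analytic fluence model, in
#' tissue-label order (background, skin, skull, CSF, gray, white).
#' Background attenuates nothing.
#'
#' @export
defaultAttenuation <- function() {
  c(background = 0, skin = 0.18, skull = 0.16, csf = 0.04,
    gray = 0.15, white = 0.20)
}

## Analytic fluence at arbitrary target points: exp(-d * mean(mu)) with mu
## sampled at S midpoints of the straight optode->target segment. The
## midpoint set is symmetric, so the value is invariant under swapping the
## endpoints -- this gives bit-exact source/detector reciprocity.
fluenceAt <- function(volume, origin, targets, attenuation, nSamples = 48L) {
  targets <- matrix(targets, ncol = 3)
  d <- sqrt(rowSums(sweep(targets, 2, origin)^2))
  dims <- dim(volume@labels)
  inv <- solve(volume@affine)
  musum <- numeric(nrow(targets))
  fr <- (seq_len(nSamples) - 0.5) / nSamples
  for (f in fr) {
    pts <- sweep(targets * f, 2, origin * (1 - f), "+")
    ijk <- floor(t(inv[1:3, 1:3] %*% t(pts)) +
                   matrix(inv[1:3, 4], nrow(pts), 3, byrow = TRUE) + 0.5)
    ok <- ijk[, 1] >= 0 & ijk[, 1] < dims[1] &
          ijk[, 2] >= 0 & ijk[, 2] < dims[2] &
          ijk[, 3] >= 0 & ijk[, 3] < dims[3]
    lab <- integer(nrow(pts))
    idx <- ijk[ok, 1] + dims[1] * (ijk[ok, 2] + dims[2] * ijk[ok, 3]) + 1
    lab[ok] <- volume@labels[idx]
    musum <- musum + attenuation[lab + 1L]
  }
  exp(-d * musum / nSamples)
}

#' Analytic synthetic fluence field
#'
#' Deterministic stand-in for photon-transport fluence: the fluence at a
#' voxel is \code{exp(-integral of tissue attenuation along the straight
#' line from the optode)}, with the line integral taken by midpoint
#' sampling. The field is 1 at the optode (zero path), nonincreasing
#' outward through homogeneous tissue, and zero outside the head mask.
#'
#' @param volume a \code{HeadVolume}.
#' @param optodePos optode position (world mm), on or near the scalp.
#' @param attenuation named per-tissue attenuation vector (mm^-1) in label
#'   order; see \code{\link{defaultAttenuation}}.
#' @param nSamples line-integral midpoint samples.
#' @param voxels optional integer linear voxel indices; when given, a plain
#'   vector of fluences at those voxels is returned instead of the full
#'   grid.
#' @return a 3-d fluence array aligned to \code{volume} (zero outside the
#'   head), with attribute \code{optode}; or a vector if \code{voxels} is
#'   given.
#' @export
syntheticFluence <- function(volume, optodePos, attenuation = NULL,
                             nSamples = 48L, voxels = NULL) {
  if (is.null(attenuation)) attenuation <- defaultAttenuation()
  checkOptodeOnScalp(volume, optodePos)
  if (is.null(voxels)) {
    inside <- which(volume@labels > 0L)
  } else inside <- voxels
  ijk <- arrayInd(inside, dim(volume@labels)) - 1L
  centers <- voxelCenters(volume, ijk)
  vals <- fluenceAt(volume, optodePos, centers, attenuation, nSamples)
  if (!is.null(voxels)) return(vals)
  out <- array(0, dim(volume@labels))
  out[inside] <- vals
  attr(out, "optode") <- optodePos
  out
}

checkOptodeOnScalp <- function(volume, pos, maxDepthMm = 5) {
  dims <- dim(volume@labels)
  center <- as.numeric(voxelCenters(volume, matrix((dims - 1) / 2, 1)))
  u <- pos - center
  nu <- sqrt(sum(u^2))
  if (nu < 1e-9) stop("geometry error: optode at the head center")
  u <- u / nu
  labelAt <- function(p) {
    ijk <- floor(worldToVoxel(volume, matrix(p, 1)) + 0.5)
    if (any(ijk < 0) || any(ijk >= dims)) return(0L)
    volume@labels[ijk[1] + dims[1] * (ijk[2] + dims[2] * ijk[3]) + 1]
  }
  if (labelAt(pos) == 0L) return(invisible(TRUE))   # outside/on the scalp
  ## walk outward; if the head boundary is farther than maxDepthMm the
  ## optode is buried in the interior
  for (step in seq(0.5, maxDepthMm, by = 0.5)) {
    if (labelAt(pos + step * u) == 0L) return(invisible(TRUE))
  }
  stop("geometry error: optode more than ", maxDepthMm,
       " mm below the scalp surface")
}

#' Adjoint (Rytov) channel sensitivity
#'
#' Voxelwise product of the source and detector fluence fields, normalized
#' by the fluence of the source field evaluated at the detector position.
#' The construction is symmetric in source and detector.
#'
#' @param sourceFluence,detectorFluence fluence arrays from
#'   \code{\link{syntheticFluence}} (or plain vectors over matching voxels).
#' @param normalizer the source fluence at the detector position; computed
#'   from the attached optode positions when both inputs are full arrays
#'   from \code{syntheticFluence}.
#' @param volume,attenuation,nSamples used to compute the normalizer when
#'   it is not supplied.
#' @return sensitivity array (or vector), same shape as the inputs.
#' @export
channelSensitivity <- function(sourceFluence, detectorFluence,
                               normalizer = NULL, volume = NULL,
                               attenuation = NULL, nSamples = 48L) {
  if (is.null(normalizer)) {
    so <- attr(sourceFluence, "optode")
    de <- attr(detectorFluence, "optode")
    if (is.null(so) || is.null(de) || is.null(volume))
      stop("supply normalizer, or full fluence arrays plus the volume")
    if (is.null(attenuation)) attenuation <- defaultAttenuation()
    normalizer <- fluenceAt(volume, so, matrix(de, 1), attenuation,
                            nSamples)
  }
  if (normalizer <= 0) stop("numeric error: zero fluence normalizer")
  out <- sourceFluence * detectorFluence / normalizer
  attr(out, "optode") <- NULL
  out
}

#' Voronoi assignment of gray-matter voxels to surface vertices
#'
#' Each gray-matter voxel is assigned to its nearest surface vertex
#' (Euclidean distance), subject to a distance cap; voxels beyond the cap
#' are recorded as unassigned.
#'
#' @param volume a \code{HeadVolume}.
#' @param surface a \code{CorticalSurface} in the same frame.
#' @param capMm assignment distance cap (default 6 mm).
#' @return a \code{\linkS4class{VoronoiMap}}.
#' @export
buildVoronoi <- function(volume, surface, capMm = 6) {
  gm <- which(volume@labels == TISSUE_LABELS[["gray"]])
  if (!length(gm)) stop("empty gray-matter mask")
  centers <- voxelCenters(volume, arrayInd(gm, dim(volume@labels)) - 1L)
  V <- surface@vertices
  n <- length(gm)
  nearest <- integer(n); ndist <- numeric(n)
  step <- max(1L, floor(2e6 / nrow(V)))
  v2 <- rowSums(V^2)
  for (s in seq(1, n, by = step)) {
    e <- min(n, s + step - 1L)
    C <- centers[s:e, , drop = FALSE]
    D2 <- outer(rowSums(C^2), v2, "+") - 2 * C %*% t(V)
    nearest[s:e] <- max.col(-D2, ties.method = "first")
    ndist[s:e] <- sqrt(pmax(D2[cbind(seq_len(e - s + 1L),
                                     nearest[s:e])], 0))
  }
  keep <- ndist <= capMm
  new("VoronoiMap", voxels = gm[keep], vertex = nearest[keep],
      unassigned = gm[!keep], dim = dim(volume@labels))
}

#' Project a voxel sensitivity map to the surface
#'
#' Vertex value = mean voxel sensitivity within the vertex's Voronoi cell;
#' vertices with empty cells get 0.
#'
#' @param voxelValues full-grid array, or a vector over
#'   \code{voronoi@voxels}.
#' @param voronoi a \code{VoronoiMap}.
#' @param nVertices total number of surface vertices.
#' @return numeric per-vertex sensitivity vector.
#' @export
projectToSurface <- function(voxelValues, voronoi, nVertices) {
  vals <- if (length(voxelValues) == length(voronoi@voxels)) {
    as.numeric(voxelValues)
  } else as.numeric(voxelValues[voronoi@voxels])
  out <- numeric(nVertices)
  sums <- rowsum(vals, voronoi@vertex)
  counts <- rowsum(rep(1, length(vals)), voronoi@vertex)
  out[as.integer(rownames(sums))] <- sums / counts
  out
}

#' Sensitivity map in log10 decades ("paper-dB")
#'
#' Maps sensitivities to \code{log10(s / max(s))}: the most sensitive
#' vertex is at 0, a vertex ten times less sensitive at -1. Note this is
#' one unit per decade (the montage-review convention used here), not the
#' conventional 10*log10 decibel.
#'
#' @param s per-vertex sensitivity (vector), or a channel x vertex matrix
#'   (then each row is normalized to its own maximum).
#' @return same shape as \code{s}, in log10 decades; zeros map to
#'   \code{-Inf}.
#' @export
sensitivityDb <- function(s) {
  if (is.matrix(s)) {
    mx <- apply(s, 1, max)
    if (any(mx <= 0)) stop("all-zero sensitivity row")
    return(log10(sweep(s, 1, mx, "/")))
  }
  if (max(s) <= 0) stop("all-zero sensitivity map")
  log10(s / max(s))
}

#' Montage-sum sensitivity map
#'
#' Sums the channel sensitivity rows and converts to log10 decades.
#'
#' @param A channel x vertex sensitivity matrix.
#' @return per-vertex montage map in log10 decades.
#' @export
montageSensitivityDb <- function(A) sensitivityDb(colSums(A))

#' Overlap: minimum sensitivity of the n most sensitive channels
#'
#' For each vertex, channel sensitivities are sorted in decreasing order
#' and the n-th value returned, i.e. the sensitivity guaranteed by the n
#' best channels.
#'
#' @param Adb channel x vertex matrix of per-channel log10-decade maps.
#' @param nChannels the overlap count n (>= 1).
#' @return per-vertex value.
#' @export
overlapMinSensitivity <- function(Adb, nChannels) {
  if (nChannels < 1L || nChannels > nrow(Adb))
    stop("nChannels must be between 1 and the channel count")
  apply(Adb, 2, function(x) sort(x, decreasing = TRUE)[nChannels])
}

#' Overlap: number of channels above a sensitivity threshold
#'
#' @param Adb channel x vertex matrix of per-channel log10-decade maps
#'   (each channel normalized to its own maximum).
#' @param thresholdDb threshold in log10 decades (default -1).
#' @return integer per-vertex channel count.
#' @export
overlapChannelCount <- function(Adb, thresholdDb = -1) {
  as.integer(colSums(Adb >= thresholdDb))
}

#' Field of view of a montage on the cortical surface
#'
#' Vertices within \code{radiusMm} (Euclidean) of any source or detector.
#'
#' @param surface a \code{CorticalSurface}.
#' @param probe a \code{Probe} in the same frame.
#' @param radiusMm inclusion radius (default 30).
#' @return integer vertex indices.
#' @export
fieldOfView <- function(surface, probe, radiusMm = 30) {
  opt <- rbind(probe@sourcePos, probe@detectorPos)
  V <- surface@vertices
  d2 <- matrix(Inf, nrow(V), 1)
  for (i in seq_len(nrow(opt)))
    d2 <- pmin(d2, rowSums(sweep(V, 2, opt[i, ])^2))
  fov <- which(d2 <= radiusMm^2)
  if (!length(fov)) stop("empty field of view")
  fov
}

#' Build the channel x vertex forward model
#'
#' Computes analytic fluences for every optode at the assigned gray-matter
#' voxels, forms the adjoint sensitivity per source-detector pair,
#' projects each onto the surface through the Voronoi map, and restricts
#' columns to the field of view.
#'
#' @param volume a \code{HeadVolume}.
#' @param surface a \code{CorticalSurface}.
#' @param probe a \code{Probe}.
#' @param attenuation per-tissue attenuation (mm^-1).
#' @param fovRadiusMm field-of-view radius.
#' @param capMm Voronoi distance cap.
#' @param nSamples line-integral samples.
#' @param noiseVar per-pair noise variances (default 1).
#' @return a \code{\linkS4class{ForwardModel}} (rows ordered as the unique
#'   source-detector pairs of the probe channel list).
#' @export
buildForwardModel <- function(volume, surface, probe, attenuation = NULL,
                              fovRadiusMm = 30, capMm = 6, nSamples = 48L,
                              noiseVar = NULL) {
  if (is.null(attenuation)) attenuation <- defaultAttenuation()
  vor <- buildVoronoi(volume, surface, capMm)
  fov <- fieldOfView(surface, probe, fovRadiusMm)
  pairs <- unique(channelTable(probe)[, c("source", "detector")])
  rownames(pairs) <- NULL
  srcFl <- lapply(seq_len(nrow(probe@sourcePos)), function(i)
    syntheticFluence(volume, probe@sourcePos[i, ], attenuation, nSamples,
                     voxels = vor@voxels))
  detFl <- lapply(seq_len(nrow(probe@detectorPos)), function(i)
    syntheticFluence(volume, probe@detectorPos[i, ], attenuation, nSamples,
                     voxels = vor@voxels))
  A <- matrix(0, nrow(pairs), length(fov))
  for (p in seq_len(nrow(pairs))) {
    s <- pairs$source[p]; d <- pairs$detector[p]
    norm <- fluenceAt(volume, probe@sourcePos[s, ],
                      matrix(probe@detectorPos[d, ], 1), attenuation,
                      nSamples)
    sens <- channelSensitivity(srcFl[[s]], detFl[[d]], normalizer = norm)
    A[p, ] <- projectToSurface(sens, vor, nrow(surface@vertices))[fov]
  }
  if (is.null(noiseVar)) noiseVar <- rep(1, nrow(pairs))
  new("ForwardModel", A = A, fov = as.integer(fov), noiseVar = noiseVar,
      pairs = pairs)
}

#' Estimate diagonal channel noise variances from a baseline window
#'
#' @param od an \code{OpticalDensity}.
#' @param baselineWindow numeric window (s); defaults to the series
#'   baseline window.
#' @return per-channel variance vector.
#' @export
estimateNoiseVar <- function(od, baselineWindow = NULL) {
  if (is.null(baselineWindow)) baselineWindow <- od@baselineWindow
  sel <- od@times >= baselineWindow[1] & od@times <= baselineWindow[2]
  if (sum(sel) < 2L) stop("baseline window too short")
  apply(od@od[, sel, drop = FALSE], 1, stats::var)
}

#' Write a per-vertex map as TSV
#'
#' @param values per-vertex values.
#' @param path output path.
#' @param vertices optional vertex indices (default all).
#' @export
writeVertexMap <- function(values, path, vertices = seq_along(values)) {
  utils::write.table(data.frame(vertex = vertices, value = values), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
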