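#' Construct a Probe
#'
#' Builds a validated \code{\linkS4class{Probe}}. If \code{channels} is
#' omitted, a full channel list is generated with one channel per
#' source-detector pair and wavelength, wavelength varying fastest.
#'
#' @param sourcePos,detectorPos numeric matrices (n x 3, mm).
#' @param wavelengths numeric vector of wavelengths (nm).
#' @param channels optional data.frame with columns source, detector,
#'   wavelength (1-based indices).
#' @param landmarks optional named matrix of fiducials (rows named).
#' @param pairs optional data.frame with columns source, detector limiting
#'   which pairs form channels when \code{channels} is not given.
#' @return a \code{Probe}.
#' @export
Probe <- function(sourcePos, detectorPos, wavelengths, channels = NULL,
                  landmarks = NULL, pairs = NULL) {
  sourcePos <- asPositionMatrix(sourcePos)
  detectorPos <- asPositionMatrix(detectorPos)
  if (is.null(channels)) {
    if (is.null(pairs))
      pairs <- expand.grid(detector = seq_len(nrow(detectorPos)),
                           source = seq_len(nrow(sourcePos)))[, 2:1]
    nw <- length(wavelengths)
    channels <- data.frame(
      source = rep(pairs$source, each = nw),
      detector = rep(pairs$detector, each = nw),
      wavelength = rep(seq_len(nw), times = nrow(pairs))
    )
  }
  channels$source <- as.integer(channels$source)
  channels$detector <- as.integer(channels$detector)
  channels$wavelength <- as.integer(channels$wavelength)
  new("Probe", sourcePos = sourcePos, detectorPos = detectorPos,
      wavelengths = as.numeric(wavelengths), channels = channels,
      landmarks = landmarks)
}

asPositionMatrix <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != 3L) stop("positions must have 3 columns")
  x
}

#' Construct an OpticalRecording
#'
#' @param probe a \code{Probe}.
#' @param times numeric sample times (s), uniform step.
#' @param intensities channel x time matrix of raw intensities.
#' @param events data.frame with columns label, onset, duration (may be empty).
#' @param channelFlags optional flags data.frame (good, reason).
#' @return an \code{OpticalRecording}.
#' @export
OpticalRecording <- function(probe, times, intensities, events = NULL,
                             channelFlags = NULL) {
  if (is.null(events))
    events <- data.frame(label = character(), onset = numeric(),
                         duration = numeric())
  if (is.null(channelFlags))
    channelFlags <- data.frame(good = rep(TRUE, nrow(probe@channels)),
                               reason = rep("", nrow(probe@channels)))
  new("OpticalRecording", probe = probe, times = as.numeric(times),
      intensities = as.matrix(intensities), events = events,
      channelFlags = channelFlags)
}

#' Least-squares rigid fiducial alignment (Kabsch)
#'
#' Maps the probe into the anatomical frame with the closed-form
#' least-squares rigid transform (3 rotations + 3 translations, no scaling)
#' that aligns the probe's named landmarks to matching fiducials. Pairwise
#' optode distances are preserved exactly (isometry).
#'
#' @param probe a \code{Probe} carrying at least 3 named landmarks.
#' @param fiducials named matrix of anatomical fiducial positions; names are
#'   matched case-insensitively against the probe landmarks.
#' @return the transformed \code{Probe}; the fitted transform is attached as
#'   attribute \code{transform} (a 4 x 4 matrix) and the landmark residual
#'   RMS as attribute \code{rms}.
#' @export
alignProbeToAnatomy <- function(probe, fiducials) {
  if (is.null(probe@landmarks)) stop("probe carries no landmarks")
  pn <- tolower(rownames(probe@landmarks))
  fn <- tolower(rownames(fiducials))
  common <- intersect(pn, fn)
  if (length(common) < 3L)
    stop("need at least 3 matching landmark pairs for rigid alignment")
  P <- probe@landmarks[match(common, pn), , drop = FALSE]
  Q <- fiducials[match(common, fn), , drop = FALSE]
  tr <- kabsch(P, Q)
  out <- probe
  out@sourcePos <- applyRigid(tr, probe@sourcePos)
  out@detectorPos <- applyRigid(tr, probe@detectorPos)
  out@landmarks <- applyRigid(tr, probe@landmarks)
  resid <- applyRigid(tr, P) - Q
  attr(out, "transform") <- tr
  attr(out, "rms") <- sqrt(mean(rowSums(resid^2)))
  out
}

#' Closed-form rigid fit between point sets
#'
#' Returns the 4 x 4 homogeneous transform (rotation + translation) that
#' maps \code{P} onto \code{Q} in the least-squares sense, via SVD of the
#' cross-covariance with the usual reflection guard.
#'
#' @param P,Q matched n x 3 point sets.
#' @return 4 x 4 transform matrix.
#' @export
kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- crossprod(sweep(P, 2, cp), sweep(Q, 2, cq))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tvec <- cq - as.numeric(R %*% cp)
  out <- diag(4)
  out[1:3, 1:3] <- R
  out[1:3, 4] <- tvec
  out
}

applyRigid <- function(transform, points) {
  if (is.null(points)) return(NULL)
  out <- t(transform[1:3, 1:3] %*% t(points)) +
    matrix(transform[1:3, 4], nrow(points), 3, byrow = TRUE)
  dimnames(out) <- dimnames(points)
  out
}

#' Construct a CorticalSurface
#'
#' @param vertices Nv x 3 matrix (mm).
#' @param faces Nf x 3 integer matrix of 1-based vertex indices.
#' @return a \code{CorticalSurface}.
#' @export
CorticalSurface <- function(vertices, faces) {
  vertices <- asPositionMatrix(vertices)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  new("CorticalSurface", vertices = vertices, faces = faces)
}

#' Mesh adjacency as an igraph graph
#'
#' Edge-weighted (Euclidean length) undirected graph over mesh vertices,
#' used for region growing and geodesic distances.
#'
#' @param surface a \code{CorticalSurface}.
#' @param vertices optional integer subset; the induced subgraph is returned
#'   with vertex names equal to the original indices.
#' @return an \code{igraph} graph.
#' @export
meshGraph <- function(surface, vertices = NULL) {
  f <- surface@faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(1, 3)])
  e <- t(apply(e, 1, sort))
  e <- unique(e)
  w <- sqrt(rowSums((surface@vertices[e[, 1], , drop = FALSE] -
                     surface@vertices[e[, 2], , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  igraph::E(g)$weight <- w
  igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  if (!is.null(vertices))
    g <- igraph::induced_subgraph(g, vertices)
  g
}

#' Vertex neighbor lists of a surface mesh
#'
#' @param surface a \code{CorticalSurface}.
#' @return list of integer neighbor vectors, one per vertex.
#' @export
vertexNeighbors <- function(surface) {
  g <- meshGraph(surface)
  lapply(igraph::adjacent_vertices(g, igraph::V(g)),
         function(v) as.integer(names(v)))
}

#' Construct a HeadVolume
#'
#' @param labels integer 3-d array of tissue labels (0..5).
#' @param voxelSize isotropic voxel edge (mm).
#' @param affine optional 4 x 4 voxel-to-world transform; defaults to
#'   scaling by \code{voxelSize} with the origin at the volume center.
#' @return a \code{HeadVolume}.
#' @export
HeadVolume <- function(labels, voxelSize, affine = NULL) {
  storage.mode(labels) <- "integer"
  if (is.null(affine)) {
    d <- dim(labels)
    affine <- diag(c(voxelSize, voxelSize, voxelSize, 1))
    affine[1:3, 4] <- -voxelSize * (d - 1) / 2
  }
  new("HeadVolume", labels = labels, voxelSize = voxelSize, affine = affine)
}

#' Voxel center world coordinates
#'
#' @param volume a \code{HeadVolume}.
#' @param ijk integer matrix of 0-based voxel indices (n x 3); defaults to
#'   all voxels in linear order.
#' @return n x 3 matrix of world coordinates (mm).
#' @export
voxelCenters <- function(volume, ijk = NULL) {
  d <- dim(volume@labels)
  if (is.null(ijk)) {
    ijk <- cbind(
      rep(0:(d[1] - 1), times = d[2] * d[3]),
      rep(rep(0:(d[2] - 1), each = d[1]), times = d[3]),
      rep(0:(d[3] - 1), each = d[1] * d[2])
    )
  }
  t(volume@affine[1:3, 1:3] %*% t(ijk)) +
    matrix(volume@affine[1:3, 4], nrow(ijk), 3, byrow = TRUE)
}

#' World coordinates to 0-based voxel indices
#'
#' @param volume a \code{HeadVolume}.
#' @param xyz n x 3 world coordinates (mm).
#' @return n x 3 matrix of fractional 0-based voxel indices.
#' @export
worldToVoxel <- function(volume, xyz) {
  inv <- solve(volume@affine)
  t(inv[1:3, 1:3] %*% t(xyz)) +
    matrix(inv[1:3, 4], nrow(xyz), 3, byrow = TRUE)
}
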