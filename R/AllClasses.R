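#' @import methods
NULL

## Coordinate convention used throughout: millimetres, RAS world frame.
## Voxel indices are 0-based at the C/world interface; see HeadVolume.

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Optode geometry of an fNIRS montage
#'
#' A \code{Probe} holds source and detector positions (mm, world frame), the
#' laser wavelengths (nm), the channel table, and optional anatomical
#' fiducial landmarks (rows named e.g. \code{nasion}, \code{lpa}, \code{rpa}).
#'
#' Channels are rows of a data frame with integer columns \code{source},
#' \code{detector}, \code{wavelength} (all 1-based indices into the
#' corresponding slots). All per-channel matrices in the package are ordered
#' as this channel list; the constructor orders wavelength fastest within
#' each source-detector pair.
#'
#' @slot sourcePos numeric matrix, one row per source (x, y, z in mm).
#' @slot detectorPos numeric matrix, one row per detector.
#' @slot wavelengths numeric vector of wavelengths in nm.
#' @slot channels data.frame with columns source, detector, wavelength.
#' @slot landmarks named numeric matrix of fiducial points, or NULL.
#' @exportClass Probe
setClass("Probe",
  representation(
    sourcePos = "matrix",
    detectorPos = "matrix",
    wavelengths = "numeric",
    channels = "data.frame",
    landmarks = "matrixOrNULL"
  )
)

setValidity("Probe", function(object) {
  msg <- character()
  if (ncol(object@sourcePos) != 3L || ncol(object@detectorPos) != 3L)
    msg <- c(msg, "source and detector positions must have 3 columns")
  ch <- object@channels
  if (!all(c("source", "detector", "wavelength") %in% names(ch)))
    msg <- c(msg, "channels must have columns source, detector, wavelength")
  else {
    if (nrow(ch)) {
      if (any(ch$source < 1L) || any(ch$source > nrow(object@sourcePos)))
        msg <- c(msg, "channel source index out of range")
      if (any(ch$detector < 1L) || any(ch$detector > nrow(object@detectorPos)))
        msg <- c(msg, "channel detector index out of range")
      if (any(ch$wavelength < 1L) ||
          any(ch$wavelength > length(object@wavelengths)))
        msg <- c(msg, "channel wavelength index out of range")
      if (anyDuplicated(ch[, c("source", "detector", "wavelength")]))
        msg <- c(msg, "duplicate (source, detector, wavelength) triples")
      d <- sqrt(rowSums((object@sourcePos[ch$source, , drop = FALSE] -
                         object@detectorPos[ch$detector, , drop = FALSE])^2))
      if (any(d <= 0))
        msg <- c(msg, "source-detector distance must be strictly positive")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Raw continuous-wave fNIRS recording
#'
#' Channel-by-time raw light intensities together with the \code{Probe},
#' sample times (s, strictly increasing, uniform step), the event table
#' (\code{label}, \code{onset}, \code{duration} in s) and per-channel
#' good/bad flags with a reason code.
#'
#' @slot probe a \code{Probe}.
#' @slot times numeric vector of sample times in seconds.
#' @slot intensities channel x time matrix of raw intensities (device units).
#' @slot events data.frame with columns label, onset, duration.
#' @slot channelFlags data.frame with columns good (logical), reason (character).
#' @exportClass OpticalRecording
setClass("OpticalRecording",
  representation(
    probe = "Probe",
    times = "numeric",
    intensities = "matrix",
    events = "data.frame",
    channelFlags = "data.frame"
  )
)

setValidity("OpticalRecording", function(object) {
  msg <- character()
  nc <- nrow(object@probe@channels)
  if (nrow(object@intensities) != nc)
    msg <- c(msg, "intensity rows must equal number of channels")
  if (ncol(object@intensities) != length(object@times))
    msg <- c(msg, "intensity columns must equal number of time samples")
  if (length(object@times) > 1L) {
    dt <- diff(object@times)
    if (any(dt <= 0))
      msg <- c(msg, "times must be strictly increasing")
    else if (diff(range(dt)) > 1e-6)
      msg <- c(msg, "sample step must be uniform within 1e-6 s")
  }
  if (nrow(object@channelFlags) != nc)
    msg <- c(msg, "channelFlags must have one row per channel")
  if (length(msg)) msg else TRUE
})

#' Optical-density time series
#'
#' Baseline-referenced optical density changes, \code{-log10(I/I0)}, per
#' channel. Carries the probe, times and events of the parent recording so
#' downstream stages need no side information.
#'
#' @slot probe a \code{Probe}.
#' @slot times sample times (s).
#' @slot od channel x time matrix of optical density change (unitless).
#' @slot events event table.
#' @slot baselineWindow numeric length-2 window (s) used for I0.
#' @slot baselineStat "mean" or "median".
#' @exportClass OpticalDensity
setClass("OpticalDensity",
  representation(
    probe = "Probe",
    times = "numeric",
    od = "matrix",
    events = "data.frame",
    baselineWindow = "numeric",
    baselineStat = "character"
  )
)

setValidity("OpticalDensity", function(object) {
  msg <- character()
  if (nrow(object@od) != nrow(object@probe@channels))
    msg <- c(msg, "od rows must equal number of channels")
  if (ncol(object@od) != length(object@times))
    msg <- c(msg, "od columns must equal number of time samples")
  if (anyNA(object@od) || any(!is.finite(object@od)))
    msg <- c(msg, "od must be finite everywhere")
  if (length(msg)) msg else TRUE
})

#' Hemoglobin concentration-change series
#'
#' Source-detector pair by time matrices of oxy-, deoxy- and total
#' hemoglobin changes in micromolar. \code{hbt} is identically
#' \code{hbo + hbr}.
#'
#' @slot pairs data.frame with columns source, detector (pair list).
#' @slot times sample times (s).
#' @slot hbo,hbr,hbt pair x time matrices (uM).
#' @slot events event table.
#' @slot probe the originating probe.
#' @exportClass HemoglobinSeries
setClass("HemoglobinSeries",
  representation(
    probe = "Probe",
    pairs = "data.frame",
    times = "numeric",
    hbo = "matrix",
    hbr = "matrix",
    hbt = "matrix",
    events = "data.frame"
  )
)

setValidity("HemoglobinSeries", function(object) {
  msg <- character()
  dims <- dim(object@hbo)
  if (!identical(dims, dim(object@hbr)) || !identical(dims, dim(object@hbt)))
    msg <- c(msg, "hbo, hbr, hbt must have identical dimensions")
  if (dims[1L] != nrow(object@pairs))
    msg <- c(msg, "row count must equal number of pairs")
  if (!identical(object@hbt, object@hbo + object@hbr))
    msg <- c(msg, "hbt must equal hbo + hbr exactly")
  if (length(msg)) msg else TRUE
})

#' Triangulated cortical surface mesh
#'
#' @slot vertices Nv x 3 matrix of vertex positions (mm).
#' @slot faces integer Nf x 3 matrix of 1-based vertex indices.
#' @exportClass CorticalSurface
setClass("CorticalSurface",
  representation(vertices = "matrix", faces = "matrix")
)

setValidity("CorticalSurface", function(object) {
  msg <- character()
  if (ncol(object@vertices) != 3L) msg <- c(msg, "vertices must be Nv x 3")
  if (ncol(object@faces) != 3L) msg <- c(msg, "faces must be Nf x 3")
  f <- object@faces
  if (nrow(f) && (min(f) < 1L || max(f) > nrow(object@vertices)))
    msg <- c(msg, "faces reference invalid vertices")
  if (length(msg)) msg else TRUE
})

#' Labeled head volume
#'
#' Voxelized head segmentation into the five standard tissues plus
#' background. Label codes: 0 background, 1 skin, 2 skull, 3 CSF,
#' 4 gray matter, 5 white matter. The affine maps homogeneous 0-based
#' voxel indices to world mm (RAS).
#'
#' @slot labels integer 3-d array of tissue labels.
#' @slot voxelSize voxel edge length in mm (isotropic).
#' @slot affine 4 x 4 voxel-to-world matrix.
#' @exportClass HeadVolume
setClass("HeadVolume",
  representation(labels = "array", voxelSize = "numeric", affine = "matrix")
)

#' @export
TISSUE_LABELS <- c(background = 0L, skin = 1L, skull = 2L, csf = 3L,
                   gray = 4L, white = 5L)

setValidity("HeadVolume", function(object) {
  msg <- character()
  if (length(dim(object@labels)) != 3L)
    msg <- c(msg, "labels must be a 3-d array")
  if (!all(unique(as.integer(object@labels)) %in% TISSUE_LABELS))
    msg <- c(msg, "labels restricted to 0..5 (background..white matter)")
  if (!identical(dim(object@affine), c(4L, 4L)) ||
      abs(det(object@affine)) < .Machine$double.eps)
    msg <- c(msg, "affine must be an invertible 4 x 4 matrix")
  if (length(msg)) msg else TRUE
})

#' Channel sensitivity forward model
#'
#' Nonnegative channel-pair x vertex sensitivity matrix restricted to the
#' field of view, with a diagonal channel noise covariance.
#'
#' @slot A channel-pair x FOV-vertex sensitivity matrix (unitless).
#' @slot fov integer indices of field-of-view vertices into the full surface.
#' @slot noiseVar per-channel noise variances (diagonal of the noise covariance).
#' @slot pairs data.frame of source/detector indices, one row per A row.
#' @exportClass ForwardModel
setClass("ForwardModel",
  representation(
    A = "matrix",
    fov = "integer",
    noiseVar = "numeric",
    pairs = "data.frame"
  )
)

setValidity("ForwardModel", function(object) {
  msg <- character()
  if (any(object@A < 0)) msg <- c(msg, "sensitivity must be nonnegative")
  if (ncol(object@A) != length(object@fov))
    msg <- c(msg, "A columns must match field-of-view size")
  if (length(object@noiseVar) != nrow(object@A) || any(object@noiseVar <= 0))
    msg <- c(msg, "noiseVar must be positive, one entry per channel")
  if (length(msg)) msg else TRUE
})

#' Voxel-to-vertex Voronoi assignment
#'
#' @slot voxels integer linear indices of assigned gray-matter voxels.
#' @slot vertex integer vertex index for each assigned voxel.
#' @slot unassigned integer linear indices of gray-matter voxels beyond the
#'   distance cap.
#' @slot dim volume grid dimensions.
#' @exportClass VoronoiMap
setClass("VoronoiMap",
  representation(voxels = "integer", vertex = "integer",
                 unassigned = "integer", dim = "integer")
)

#' Cortical parcellation for the maximum-entropy prior
#'
#' @slot assignment integer parcel id per FOV vertex.
#' @slot parcels list of integer vertex-index vectors (into the FOV), one per parcel.
#' @slot mspScores per-vertex prelocalization scores in [0, 1].
#' @slot neighborhoodOrder the tuned region-growing geodesic radius (mm).
#' @exportClass Parcellation
setClass("Parcellation",
  representation(assignment = "integer", parcels = "list",
                 mspScores = "numeric", neighborhoodOrder = "numeric")
)

setValidity("Parcellation", function(object) {
  msg <- character()
  n <- length(object@assignment)
  cover <- sort(unlist(object@parcels, use.names = FALSE))
  if (!identical(cover, seq_len(n)))
    msg <- c(msg, "parcels must partition the field of view")
  if (length(msg)) msg else TRUE
})

#' Bernoulli-Gaussian prior for the maximum-entropy solver
#'
#' Per parcel k the prior on the parcel source vector is
#' (1 - alpha_k) * Dirac(0) + alpha_k * N(0, eta_k(t) * C_k) with
#' C_k = W' Lambda W a fixed smoothness/depth structure and eta_k(t) a
#' per-sample energy scale.
#'
#' @slot parcellation the \code{Parcellation}.
#' @slot alpha per-parcel activation probability in [0, 1].
#' @slot Ck list of per-parcel structure matrices W' Lambda W.
#' @slot eta parcel x time matrix of energy scales.
#' @slot sigma diffusion smoothness parameter used to build W.
#' @slot omega depth-weighting exponent used for Lambda.
#' @exportClass MEMPrior
setClass("MEMPrior",
  representation(parcellation = "Parcellation", alpha = "numeric",
                 Ck = "list", eta = "matrix", sigma = "numeric",
                 omega = "numeric")
)

setValidity("MEMPrior", function(object) {
  msg <- character()
  if (any(object@alpha < 0 | object@alpha > 1))
    msg <- c(msg, "alpha must lie in [0, 1]")
  K <- length(object@parcellation@parcels)
  if (length(object@alpha) != K || length(object@Ck) != K ||
      nrow(object@eta) != K)
    msg <- c(msg, "alpha, C and eta must have one entry per parcel")
  if (length(msg)) msg else TRUE
})

#' Maximum-entropy reconstruction result
#'
#' @slot lambda channel x time matrix of dual variables at the optimum.
#' @slot alphaStar parcel x time posterior activation probabilities.
#' @slot j FOV-vertex x time source estimate.
#' @slot dualValue per-sample dual objective at the optimum.
#' @slot converged logical per sample.
#' @slot iterations integer per sample.
#' @exportClass MEMSolution
setClass("MEMSolution",
  representation(lambda = "matrix", alphaStar = "matrix", j = "matrix",
                 dualValue = "numeric", converged = "logical",
                 iterations = "integer")
)

#' Per-channel GLM fit
#'
#' @slot beta regressor x channel matrix of estimated weights.
#' @slot betaCov list of per-channel covariance matrices of beta.
#' @slot sigma2 per-channel residual variance.
#' @slot dof residual degrees of freedom.
#' @slot serial serial-correlation handling: none, precolor or prewhiten.
#' @slot rho per-channel AR(1) coefficient (prewhitening only, else NA).
#' @slot X the design matrix used (after assembly, before whitening).
#' @slot regressors regressor names.
#' @exportClass GLMResult
setClass("GLMResult",
  representation(beta = "matrix", betaCov = "list", sigma2 = "numeric",
                 dof = "numeric", serial = "character", rho = "numeric",
                 X = "matrix", regressors = "character")
)

setValidity("GLMResult", function(object) {
  msg <- character()
  if (any(object@dof <= 0)) msg <- c(msg, "dof must be positive")
  for (V in object@betaCov) {
    if (max(abs(V - t(V))) > 1e-8) {
      msg <- c(msg, "betaCov must be symmetric"); break
    }
  }
  if (length(msg)) msg else TRUE
})

#' Optode placement problem
#'
#' @slot positions candidate scalp positions (P x 3, mm).
#' @slot V P x P matrix; V[p, q] is the summed ROI sensitivity of a channel
#'   with source at p and detector at q.
#' @slot nSources,nDetectors equipment counts.
#' @slot dMin,dMax channel source-detector distance range (mm).
#' @slot optMin minimum distance between any two chosen optodes (mm).
#' @slot adjacency minimum number of channels per source.
#' @slot excluded integer indices of reserved positions.
#' @exportClass MontageProblem
setClass("MontageProblem",
  representation(positions = "matrix", V = "matrix",
                 nSources = "integer", nDetectors = "integer",
                 dMin = "numeric", dMax = "numeric", optMin = "numeric",
                 adjacency = "integer", excluded = "integer")
)

setValidity("MontageProblem", function(object) {
  msg <- character()
  if (any(object@V < 0)) msg <- c(msg, "V must be nonnegative")
  if (object@dMin >= object@dMax) msg <- c(msg, "dMin must be < dMax")
  if (object@nSources < 1L || object@nDetectors < 1L)
    msg <- c(msg, "equipment counts must be >= 1")
  if (!identical(dim(object@V),
                 c(nrow(object@positions), nrow(object@positions))))
    msg <- c(msg, "V must be P x P")
  if (length(msg)) msg else TRUE
})

#' Optode placement solution
#'
#' @slot sources,detectors integer indices of the chosen positions.
#' @slot channels data.frame of realized channels (source, detector, distance, value).
#' @slot objective total ROI sensitivity of the realized channels.
#' @slot status "optimal" or "infeasible".
#' @exportClass MontageSolution
setClass("MontageSolution",
  representation(sources = "integer", detectors = "integer",
                 channels = "data.frame", objective = "numeric",
                 status = "character")
)
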