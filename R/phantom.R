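## Layered-sphere head phantom and simulation harness: nested-sphere tissue
## volume, icosphere cortical mesh, ring probe, task-evoked hemodynamics
## with structured physiological noise, and reconstruction validation
## metrics.

#' Icosphere mesh
#'
#' Subdivided icosahedron projected onto a sphere.
#'
#' @param subdivisions subdivision level (0 = icosahedron; 4 gives 2562
#'   vertices).
#' @param radius sphere radius (mm).
#' @return a \code{CorticalSurface}.
#' @export
icosphere <- function(subdivisions = 3L, radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    mid <- new.env(parent = emptyenv())
    getMid <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      if (!is.null(mid[[key]])) return(mid[[key]])
      v <<- rbind(v, (v[a, ] + v[b, ]) / 2)
      mid[[key]] <- nrow(v)
      nrow(v)
    }
    nf <- matrix(0L, 0, 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
      ab <- getMid(a, b); bc <- getMid(b, cc); ca <- getMid(cc, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc),
                  c(ab, bc, ca))
    }
    f <- nf
  }
  v <- v / sqrt(rowSums(v^2)) * radius
  CorticalSurface(v, f)
}

sph2cart <- function(thetaDeg, phiDeg, r) {
  th <- thetaDeg * pi / 180; ph <- phiDeg * pi / 180
  r * c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
}

#' Build the layered-sphere head phantom
#'
#' Nested spheres (skin > skull > CSF > gray > white) voxelized on an
#' isotropic grid, an icosphere cortical mesh placed mid-gray-matter, and
#' a two-ring probe (8 sources, 8 detectors, all long channels 25-30 mm)
#' with 2 extra short-separation detectors 8 mm from two of the sources.
#' The construction is fully deterministic.
#'
#' @param radiiMm named outer radii per tissue, strictly nested
#'   (skin > skull > csf > gray > white).
#' @param voxelSizeMm isotropic voxel size (default 2).
#' @param meshSubdivisions icosphere subdivision level (default 4, 2562
#'   vertices).
#' @param wavelengths the two wavelengths (nm).
#' @return list with elements \code{volume} (\code{HeadVolume}),
#'   \code{surface} (\code{CorticalSurface}) and \code{probe}
#'   (\code{Probe}).
#' @export
makePhantom <- function(radiiMm = c(skin = 92, skull = 85, csf = 81,
                                    gray = 78, white = 65),
                        voxelSizeMm = 2, meshSubdivisions = 4L,
                        wavelengths = c(685, 830)) {
  r <- radiiMm[c("skin", "skull", "csf", "gray", "white")]
  if (any(diff(r) >= 0)) stop("radii must be strictly nested")
  n <- 2L * ceiling(r[["skin"]] / voxelSizeMm) + 3L
  ax <- (seq_len(n) - (n + 1) / 2) * voxelSizeMm
  dist <- sqrt(outer(outer(ax^2, ax^2, "+"), ax^2, "+"))
  lab <- array(0L, dim = c(n, n, n))
  lab[dist <= r[["skin"]]] <- TISSUE_LABELS[["skin"]]
  lab[dist <= r[["skull"]]] <- TISSUE_LABELS[["skull"]]
  lab[dist <= r[["csf"]]] <- TISSUE_LABELS[["csf"]]
  lab[dist <= r[["gray"]]] <- TISSUE_LABELS[["gray"]]
  lab[dist <= r[["white"]]] <- TISSUE_LABELS[["white"]]
  volume <- HeadVolume(lab, voxelSizeMm)

  meshR <- (r[["gray"]] + r[["white"]]) / 2
  surface <- icosphere(meshSubdivisions, meshR)

  scalpR <- r[["skin"]]
  srcAz <- 45 * (0:7)
  src <- t(vapply(srcAz, function(a) sph2cart(15, a, scalpR), numeric(3)))
  det <- t(vapply(srcAz + 22.5, function(a) sph2cart(30, a, scalpR),
                  numeric(3)))
  ## short-separation detectors: 8 mm (polar offset) from sources 1 and 5
  dTh <- 2 * asin(4 / scalpR) * 180 / pi
  det <- rbind(det, sph2cart(15 + dTh, 0, scalpR),
               sph2cart(15 + dTh, 180, scalpR))
  dd <- sqrt(outer(rowSums(src^2), rowSums(det^2), "+") -
               2 * src %*% t(det))
  ## long channels between the rings; short detectors pair only with their
  ## own source
  idx <- which(dd[, 1:8, drop = FALSE] >= 15 & dd[, 1:8, drop = FALSE] <= 35,
               arr.ind = TRUE)
  pairs <- rbind(data.frame(source = idx[, 1], detector = idx[, 2]),
                 data.frame(source = c(1L, 5L), detector = c(9L, 10L)))
  pairs <- pairs[order(pairs$source, pairs$detector), ]
  rownames(pairs) <- NULL
  probe <- Probe(src, det, wavelengths, pairs = pairs)
  list(volume = volume, surface = surface, probe = probe)
}

#' Default simulation settings
#'
#' Study conditions of the simulation harness: a 10 Hz recording with 10
#' task blocks of 10 s separated by 30 s rest, evoked amplitudes +10/-3 uM
#' (HbO/HbR) in the active patch, cardiac/respiratory/Mayer sinusoids,
#' AR(1) drift, a shared superficial component, 4 motion spikes, and
#' signal-to-noise ratio 5 (peak evoked channel optical density over the
#' per-channel noise standard deviation).
#'
#' @return a list of simulation parameters.
#' @export
defaultSimulation <- function() {
  list(
    fs = 10, nBlocks = 20, blockDurS = 10, restRangeS = c(30, 60),
    preS = 20,
    ampHbO = 10, ampHbR = -3,          # uM on the cortical patch
    roiRadiusMm = 12,
    cardiacHz = 1.1, cardiacAmp = 0.4,
    respHz = 0.25, respAmp = 0.2,
    mayerHz = 0.1, mayerAmp = 0.25,
    ar1Rho = 0.95, ar1Amp = 0.3,
    superficialAmp = 0.6,
    motionSpikes = 4, motionAmp = 3,
    snr = 5
  )
}

#' Simulate a task recording on the phantom
#'
#' Forward generative model: a boxcar event train convolved with the
#' canonical HRF drives HbO/HbR changes in a cortical patch; the
#' surface-level Beer-Lambert relation gives per-wavelength cortical
#' optical density; the forward matrix projects it to channels; structured
#' noise (cardiac, respiratory, Mayer waves, AR(1) drift, a shared
#' superficial component, motion spikes) is added at the stated SNR; and
#' intensities are synthesized as \code{I0 * 10^(-od)}.
#'
#' @param phantom output of \code{\link{makePhantom}}.
#' @param forward a \code{ForwardModel} built on the phantom.
#' @param sim simulation settings (see \code{\link{defaultSimulation}}).
#' @param seed RNG seed; the realization is reproducible given the seed.
#' @param roiCenterVertex seed vertex of the active patch (default: FOV
#'   vertex closest to the midpoint between the first source and its first
#'   in-range detector).
#' @return list: \code{recording} (\code{OpticalRecording}) and
#'   \code{truth} (ROI vertices, cortical hemoglobin and per-wavelength
#'   optical-density timecourses, channel-level noise-free OD, task
#'   course, noise scale).
#' @export
simulateRecording <- function(phantom, forward, sim = defaultSimulation(),
                              seed = 1L, roiCenterVertex = NULL) {
  set.seed(seed)
  pr <- phantom$probe
  surf <- phantom$surface
  fov <- forward@fov
  fs <- sim$fs
  ## task blocks separated by jittered rest (as in typical block designs;
  ## jitter also prevents oscillatory noise from phase-locking to epochs)
  rests <- stats::runif(sim$nBlocks, sim$restRangeS[1], sim$restRangeS[2])
  rests <- round(rests * fs) / fs
  onsets <- sim$preS + cumsum(c(0, (sim$blockDurS + rests)[-sim$nBlocks]))
  duration <- max(onsets) + sim$blockDurS + sim$restRangeS[2]
  times <- seq(0, duration - 1 / fs, by = 1 / fs)
  n <- length(times)
  events <- data.frame(label = "task", onset = onsets,
                       duration = sim$blockDurS)

  ## task timecourse, unit peak
  h <- canonicalHrf(1 / fs)
  box <- numeric(n)
  for (o in onsets)
    box[times >= o - 1e-9 & times <= o + sim$blockDurS + 1e-9] <- 1
  tc <- convolveTrunc(box, h) / fs
  tc <- tc / max(tc)

  ## active patch: geodesic ball around the seed vertex
  if (is.null(roiCenterVertex)) {
    target <- (pr@sourcePos[1, ] + pr@detectorPos[1, ]) / 2
    d2 <- rowSums(sweep(surf@vertices[fov, , drop = FALSE], 2, target)^2)
    roiCenterVertex <- fov[which.min(d2)]
  }
  g <- meshGraph(surf)
  gd <- as.numeric(igraph::distances(g, v = as.character(roiCenterVertex)))
  roi <- which(gd <= sim$roiRadiusMm)
  roiFov <- intersect(roi, fov)
  if (!length(roiFov)) stop("active patch does not intersect the FOV")

  ## cortical hemoglobin and per-wavelength optical density
  eps <- extinctionCoefficients(pr@wavelengths)
  nFov <- length(fov)
  patch <- as.numeric(fov %in% roiFov)
  jHbo <- outer(patch * sim$ampHbO, tc)
  jHbr <- outer(patch * sim$ampHbR, tc)
  jOd <- lapply(1:2, function(w)
    eps[w, "hbo"] * jHbo + eps[w, "hbr"] * jHbr)

  ## channel-level noise-free OD (per wavelength, pair order)
  mClean <- lapply(jOd, function(J) forward@A %*% J)

  ch <- pr@channels
  pairKey <- paste(forward@pairs$source, forward@pairs$detector)
  chPair <- match(paste(ch$source, ch$detector), pairKey)
  odClean <- matrix(0, nrow(ch), n)
  for (i in seq_len(nrow(ch)))
    odClean[i, ] <- mClean[[ch$wavelength[i]]][chPair[i], ]

  ## structured noise, unit scale, then scaled to the target SNR. The
  ## oscillatory physiology (cardiac, respiration, Mayer waves) is shared
  ## between the two wavelengths of a pair -- both sample the same tissue
  ## -- so the scalp coupling index of a clean simulated pair is high.
  nCh <- nrow(ch)
  superf <- cumsum(stats::rnorm(n)) / sqrt(n)
  superf <- superf - mean(superf)
  pairsAll <- unique(ch[, c("source", "detector")])
  pairNoise <- matrix(0, nrow(pairsAll), n)
  for (p in seq_len(nrow(pairsAll))) {
    phase <- stats::runif(3, 0, 2 * pi)
    pairNoise[p, ] <-
      sim$cardiacAmp * sin(2 * pi * sim$cardiacHz * times + phase[1]) +
      sim$respAmp * sin(2 * pi * sim$respHz * times + phase[2]) +
      sim$mayerAmp * sin(2 * pi * sim$mayerHz * times + phase[3]) +
      sim$superficialAmp * superf
  }
  chPairAll <- match(paste(ch$source, ch$detector),
                     paste(pairsAll$source, pairsAll$detector))
  noise <- matrix(0, nCh, n)
  for (i in seq_len(nCh)) {
    ar <- stats::filter(stats::rnorm(n), sim$ar1Rho, "recursive")
    ar <- as.numeric(ar) * sqrt(1 - sim$ar1Rho^2)
    noise[i, ] <- pairNoise[chPairAll[i], ] + sim$ar1Amp * ar
  }
  if (sim$motionSpikes > 0) {
    for (s in seq_len(sim$motionSpikes)) {
      i <- sample(nCh, 1); t0 <- sample(n - 20, 1)
      spike <- sim$motionAmp * exp(-(0:19) / 4) *
        sign(stats::rnorm(1))
      noise[i, t0 + 0:19] <- noise[i, t0 + 0:19] + spike
    }
  }
  peak <- max(abs(odClean))
  sdNoise <- mean(apply(noise, 1, stats::sd))
  scale <- if (sdNoise > 0) peak / (sim$snr * sdNoise) else 0
  od <- odClean + scale * noise

  I0 <- 1e4
  intens <- I0 * 10^(-od)
  rec <- OpticalRecording(pr, times, intens, events = events)
  list(recording = rec,
       truth = list(roi = roiFov, roiAll = roi, fov = fov, tc = tc,
                    jHbo = jHbo, jHbr = jHbr, jOd = jOd,
                    odClean = odClean, noiseScale = scale,
                    seedVertex = roiCenterVertex))
}

#' Spatial dispersion of a reconstructed map
#'
#' Energy-weighted spread (mm) around the ground truth:
#' \code{sqrt(sum(d_i^2 j_i^2) / sum(j_i^2))} where \code{d_i} is 0 inside
#' the truth set and otherwise the geodesic distance to the nearest truth
#' vertex.
#'
#' @param jMap per-vertex map values (on \code{vertices}).
#' @param truthVertices integer truth vertex ids (full-surface indexing).
#' @param surface the \code{CorticalSurface}.
#' @param vertices vertex ids corresponding to \code{jMap} (default: all).
#' @return dispersion in mm (\code{NA} for an all-zero map).
#' @export
spatialDispersion <- function(jMap, truthVertices, surface,
                              vertices = seq_len(nrow(surface@vertices))) {
  if (all(jMap == 0)) return(NA_real_)
  g <- meshGraph(surface)
  dmat <- igraph::distances(g, v = as.character(truthVertices),
                            to = as.character(vertices))
  d <- apply(dmat, 2, min)
  d[vertices %in% truthVertices] <- 0
  sqrt(sum(d^2 * jMap^2) / sum(jMap^2))
}

#' Rank-based ROC area of a map against ground truth
#'
#' Threshold-free AUC of \code{|map|} as a classifier of truth membership
#' (Mann-Whitney statistic with midrank tie handling).
#'
#' @param mapAbs per-vertex scores (absolute values are taken).
#' @param truth logical or index vector of truth membership over the map.
#' @return AUC in [0, 1].
#' @export
rocAuc <- function(mapAbs, truth) {
  x <- abs(mapAbs)
  lab <- if (is.logical(truth)) truth else seq_along(x) %in% truth
  n1 <- sum(lab); n0 <- sum(!lab)
  if (n1 == 0L || n0 == 0L)
    stop("degenerate truth: need both positive and negative vertices")
  r <- rank(x)
  (sum(r[lab]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' End-to-end phantom benchmark of the two reconstruction methods
#'
#' Builds the phantom and forward model, simulates a seeded task
#' recording, epoch-averages the optical density, reconstructs the
#' averaged response with the depth-weighted minimum-norm and the
#' maximum-entropy solvers at both wavelengths, converts to hemoglobin
#' maps, and scores spatial dispersion and ROC-AUC at the response peak.
#'
#' @param seed RNG seed for the simulated recording.
#' @param snr per-channel signal-to-noise ratio of the simulation.
#' @param phantom,forward optionally precomputed to amortize repeated runs.
#' @param sim simulation settings override.
#' @param omega depth weighting used in reconstruction.
#' @return data.frame with one row per method: spatial dispersion (mm),
#'   ROC-AUC, peak latency (s) and recovered/true amplitude ratio.
#' @export
endToEndBenchmark <- function(seed = 42L, snr = 5, phantom = NULL,
                              forward = NULL, sim = NULL, omega = 0.3) {
  if (is.null(phantom)) phantom <- makePhantom()
  if (is.null(forward))
    forward <- buildForwardModel(phantom$volume, phantom$surface,
                                 phantom$probe)
  if (is.null(sim)) sim <- defaultSimulation()
  sim$snr <- snr
  simOut <- simulateRecording(phantom, forward, sim, seed = seed)
  rec <- simOut$recording
  truth <- simOut$truth
  pr <- phantom$probe

  od <- toOpticalDensity(rec, baselineWindow = c(0, sim$preS))
  od <- bandpassFilter(od, 0, 0.5)       # lowpass leaves the slow response
  ep <- epochAverage(od, window = c(-5, sim$blockDurS + 20),
                     baselineCorrect = TRUE)$task
  ch <- channelTable(pr)
  pairKey <- paste(forward@pairs$source, forward@pairs$detector)
  m <- lapply(1:2, function(w) {
    sel <- which(ch$wavelength == w)
    rows <- match(pairKey, paste(ch$source[sel], ch$detector[sel]))
    ep$mean[sel[rows], , drop = FALSE]
  })
  nv <- lapply(1:2, function(w) {
    sel <- which(ch$wavelength == w)
    rows <- match(pairKey, paste(ch$source[sel], ch$detector[sel]))
    pmax(estimateNoiseVar(od)[sel[rows]], 1e-12) / ep$n
  })
  peakIdx <- which.max(colSums(m[[2]]^2) + colSums(m[[1]]^2))

  recon <- list()
  for (method in c("mne", "cmem")) {
    jw <- lapply(1:2, function(w) {
      if (method == "mne")
        mneSolve(m[[w]], forward@A, kappa = "lcurve", omega = omega,
                 noiseVar = nv[[w]])$j
      else
        cmemSolve(m[[w]], forward@A, phantom$surface, forward@fov,
                  noiseVar = nv[[w]], omega = omega)@j
    })
    hb <- surfaceMbll(jw[[1]], jw[[2]], wavelengths = pr@wavelengths)
    map <- abs(hb$hbo[, peakIdx])
    sd <- spatialDispersion(map, truth$roi, phantom$surface,
                            vertices = forward@fov)
    auc <- rocAuc(map, match(truth$roi, forward@fov))
    tcRec <- colMeans(hb$hbo[match(truth$roi, forward@fov), ,
                             drop = FALSE])
    peakLat <- ep$time[which.max(abs(tcRec))]
    ampRatio <- max(abs(tcRec)) / sim$ampHbO
    recon[[method]] <- data.frame(method = method,
                                  spatialDispersion = sd, rocAuc = auc,
                                  peakLatency = peakLat,
                                  amplitudeRatio = ampRatio)
  }
  out <- do.call(rbind, recon)
  rownames(out) <- NULL
  attr(out, "seed") <- seed
  out
}
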