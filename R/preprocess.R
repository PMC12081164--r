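#' Convert raw intensities to optical density
#'
#' \code{dOD = -log10(I / I0)} per channel, with \code{I0} the mean (or
#' median) intensity over the baseline window.
#'
#' @param recording an \code{OpticalRecording}; retained channels must be
#'   strictly positive throughout.
#' @param baselineWindow numeric length-2 window (s); defaults to the whole
#'   recording.
#' @param stat \code{"mean"} or \code{"median"}.
#' @return an \code{\linkS4class{OpticalDensity}}.
#' @export
toOpticalDensity <- function(recording, baselineWindow = NULL,
                             stat = c("mean", "median")) {
  stat <- match.arg(stat)
  times <- recording@times
  if (is.null(baselineWindow)) baselineWindow <- range(times)
  sel <- times >= baselineWindow[1] & times <= baselineWindow[2]
  if (!any(sel)) stop("empty baseline window")
  I <- recording@intensities
  if (any(I <= 0))
    stop("nonpositive intensities present; prune bad channels first")
  I0 <- if (stat == "mean") rowMeans(I[, sel, drop = FALSE])
        else apply(I[, sel, drop = FALSE], 1, stats::median)
  od <- -log10(I / I0)
  new("OpticalDensity", probe = recording@probe, times = times, od = od,
      events = recording@events, baselineWindow = as.numeric(baselineWindow),
      baselineStat = stat)
}

## Zero-phase filtering core. The signal is demeaned first (the constant
## belongs to the stopband of every band involving a highpass edge); for a
## pure lowpass the mean is restored afterwards.
zeroPhaseFilter <- function(x, fs, lowHz, highHz = NA, design = "iir",
                            order = NULL) {
  nyq <- fs / 2
  if (!is.na(highHz) && highHz >= nyq)
    stop("band outside Nyquist range")
  type <- if (is.na(highHz)) {
    if (lowHz <= 0) stop("band outside Nyquist range")
    "high"
  } else if (lowHz <= 0) "low" else "pass"
  W <- switch(type,
              low = highHz / nyq,
              high = lowHz / nyq,
              pass = c(lowHz, highHz) / nyq)
  if (any(W <= 0) || any(W >= 1)) stop("band outside Nyquist range")
  m <- mean(x)
  xc <- x - m
  if (design == "iir") {
    if (is.null(order)) order <- 3
    flt <- signal::butter(order, W, type = type)
    y <- signal::filtfilt(flt, xc)
  } else if (design == "fir") {
    if (is.null(order)) order <- 128
    b <- signal::fir1(order, W, type = type)
    y <- signal::filtfilt(b, xc)
  } else stop("design must be 'fir' or 'iir'")
  if (type == "low") y <- y + m
  y
}

applyRowwise <- function(series, fun) {
  if (is(series, "OpticalDensity")) {
    series@od <- t(apply(series@od, 1, fun))
    series
  } else if (is(series, "HemoglobinSeries")) {
    series@hbo <- t(apply(series@hbo, 1, fun))
    series@hbr <- t(apply(series@hbr, 1, fun))
    series@hbt <- series@hbo + series@hbr
    series
  } else if (is.matrix(series)) {
    t(apply(series, 1, fun))
  } else stop("unsupported series type")
}

#' Zero-phase bandpass / lowpass / highpass filtering
#'
#' IIR (Butterworth, default third order) or linear-phase FIR design, both
#' applied forward-backward so the net filter has zero phase. Setting
#' \code{lowHz = 0} gives a lowpass; \code{highHz = NA} gives a highpass.
#'
#' @param series an \code{OpticalDensity}, \code{HemoglobinSeries}, or a
#'   channel x time matrix (then \code{fs} is required).
#' @param lowHz,highHz band edges in Hz (0 <= low < high < Nyquist).
#' @param design \code{"iir"} or \code{"fir"}.
#' @param order filter order; defaults to 3 (IIR) or 128 (FIR).
#' @param fs sampling rate, only for matrix input.
#' @return the filtered series, same class as the input.
#' @export
bandpassFilter <- function(series, lowHz, highHz = NA,
                           design = c("iir", "fir"), order = NULL,
                           fs = NULL) {
  design <- match.arg(design)
  if (is.null(fs)) {
    if (is.matrix(series)) stop("fs is required for matrix input")
    fs <- samplingRate(series)
  }
  if (!is.na(highHz) && lowHz >= highHz) stop("need lowHz < highHz")
  applyRowwise(series, function(x)
    zeroPhaseFilter(x, fs, lowHz, highHz, design, order))
}

#' Discrete-cosine detrending
#'
#' Removes slow drifts by regressing out (ordinary least squares) the
#' discrete cosine basis functions whose period exceeds
#' \code{periodCutoffS}, together with the constant.
#'
#' @param series an \code{OpticalDensity}, \code{HemoglobinSeries} or
#'   channel x time matrix.
#' @param periodCutoffS period cutoff in seconds (default 200, i.e. remove
#'   components below 0.005 Hz).
#' @param fs sampling rate for matrix input.
#' @return the detrended series.
#' @export
dctDetrend <- function(series, periodCutoffS = 200, fs = NULL) {
  if (is.null(fs)) {
    if (is.matrix(series)) stop("fs is required for matrix input")
    fs <- samplingRate(series)
  }
  n <- if (is.matrix(series)) ncol(series)
       else length(series@times)
  duration <- n / fs
  if (duration <= periodCutoffS)
    stop("series must be longer than the period cutoff")
  kMax <- floor(2 * duration / periodCutoffS - 1e-9)
  i <- seq_len(n)
  X <- cbind(1, vapply(seq_len(kMax), function(k)
    cos(pi * k * (2 * i - 1) / (2 * n)), numeric(n)))
  Q <- qr.Q(qr(X))
  applyRowwise(series, function(x) x - Q %*% crossprod(Q, x))
}

#' Spline-interpolation motion correction
#'
#' Within each user-marked artifact window the slow artifact course is
#' modeled with a discrete cubic smoothing spline (Whittaker form of the
#' csaps-style penalty, smoothing parameter \code{smoothing}) and
#' subtracted; the corrected segment is re-leveled with a linear offset so
#' both edges join the untouched neighboring samples. Samples outside the
#' windows are returned bit-identically.
#'
#' @param od an \code{OpticalDensity}.
#' @param artifactWindows list of numeric length-2 windows (s); overlapping
#'   windows are merged with a warning.
#' @param smoothing smoothing parameter p in (0, 1); larger follows the data
#'   more closely (default 0.99).
#' @return the corrected \code{OpticalDensity}.
#' @export
splineMotionCorrect <- function(od, artifactWindows, smoothing = 0.99) {
  if (!length(artifactWindows)) return(od)
  w <- do.call(rbind, lapply(artifactWindows, function(x) sort(x[1:2])))
  w <- w[order(w[, 1]), , drop = FALSE]
  merged <- w[1, , drop = FALSE]
  for (i in seq_len(nrow(w))[-1]) {
    last <- nrow(merged)
    if (w[i, 1] <= merged[last, 2]) {
      warning("overlapping artifact windows merged")
      merged[last, 2] <- max(merged[last, 2], w[i, 2])
    } else merged <- rbind(merged, w[i, ])
  }
  times <- od@times
  ## csaps-style penalty weight, in sample units as in the reference
  ## spline-interpolation implementations: p = 0.99 tracks the artifact
  ## course closely and leaves only fast fluctuations in the residual
  mu <- (1 - smoothing) / smoothing
  X <- od@od
  for (i in seq_len(nrow(merged))) {
    idx <- which(times >= merged[i, 1] & times <= merged[i, 2])
    if (length(idx) < 4L) next
    fitMat <- whittakerOperator(length(idx), mu)
    pre <- if (min(idx) > 1L) min(idx) - 1L else NA
    post <- if (max(idx) < length(times)) max(idx) + 1L else NA
    for (chn in seq_len(nrow(X))) {
      seg <- X[chn, idx]
      fit <- as.numeric(fitMat %*% seg)
      corr <- seg - fit
      dStart <- if (is.na(pre)) 0 else X[chn, pre] - corr[1]
      dEnd <- if (is.na(post)) dStart else X[chn, post] - corr[length(corr)]
      if (is.na(pre)) dStart <- dEnd
      corr <- corr + seq(dStart, dEnd, length.out = length(corr))
      X[chn, idx] <- corr
    }
  }
  od@od <- X
  od
}

## Smoothing operator (I + mu * D2' D2)^-1 for a segment of length n.
whittakerOperator <- function(n, mu) {
  D <- diff(diag(n), differences = 2)
  solve(diag(n) + mu * crossprod(D))
}

#' Temporal derivative distribution repair (TDDR)
#'
#' Automatic motion correction: the temporal derivative of the
#' low-frequency component (below 0.5 Hz) of each channel is robustly
#' re-weighted with an iterative Tukey biweight location estimate (tuning
#' constant 4.685), re-integrated, and the untouched high-frequency
#' component and the signal mean are added back. The output mean matches
#' the input mean to numerical precision.
#'
#' @param od an \code{OpticalDensity} (uniform sampling).
#' @param tol convergence tolerance on the weight/location iteration.
#' @return the corrected \code{OpticalDensity}.
#' @export
tddrMotionCorrect <- function(od, tol = 1e-8) {
  if (any(!is.finite(od@od))) stop("non-finite samples in input")
  fs <- samplingRate(od)
  od@od <- t(apply(od@od, 1, tddrChannel, fs = fs, tol = tol))
  od
}

tddrChannel <- function(x, fs, tol = 1e-8, tune = 4.685) {
  if (fs > 1) {
    low <- zeroPhaseFilter(x, fs, 0, 0.5, design = "iir", order = 3)
  } else low <- x
  high <- x - low
  d <- diff(low)
  w <- rep(1, length(d))
  mu <- Inf
  for (iter in seq_len(50L)) {
    mu0 <- mu
    mu <- sum(w * d) / sum(w)
    dev <- abs(d - mu)
    sigma <- 1.4826 * stats::median(dev)
    if (sigma < .Machine$double.eps) { w <- as.numeric(dev == 0); break }
    r <- dev / (sigma * tune)
    w <- ((1 - r^2) * (r < 1))^2
    if (is.finite(mu0) && abs(mu - mu0) <= tol * max(abs(mu), abs(mu0), 1))
      break
  }
  newD <- w * (d - mu)
  lowCorr <- cumsum(c(0, newD))
  lowCorr <- lowCorr - mean(lowCorr) + mean(low)
  lowCorr + high
}

#' Short-separation channel regression
#'
#' Regresses the mean superficial signal out of every long channel by
#' ordinary least squares (intercept included), separately per wavelength
#' (optical density) or per chromophore (hemoglobin). Short channels are
#' passed through unchanged.
#'
#' @param series an \code{OpticalDensity} or \code{HemoglobinSeries}.
#' @param shortDistanceMaxMm maximum source-detector distance (mm) for a
#'   channel to count as a short/superficial channel (default 10).
#' @return the regressed series.
#' @export
shortChannelRegress <- function(series, shortDistanceMaxMm = 10) {
  d <- channelDistances(probe(series))
  if (is(series, "OpticalDensity")) {
    ch <- channelTable(series)
    isShort <- d <= shortDistanceMaxMm
    if (!any(isShort))
      stop("no short channels within ", shortDistanceMaxMm,
           " mm; skip this step")
    X <- series@od
    for (wl in unique(ch$wavelength)) {
      sel <- ch$wavelength == wl
      X[sel & !isShort, ] <- regressOut(
        X[sel & !isShort, , drop = FALSE],
        colMeans(X[sel & isShort, , drop = FALSE]))
    }
    series@od <- X
  } else if (is(series, "HemoglobinSeries")) {
    pd <- pairDistances(series)
    isShort <- pd <= shortDistanceMaxMm
    if (!any(isShort))
      stop("no short channels within ", shortDistanceMaxMm,
           " mm; skip this step")
    series@hbo[!isShort, ] <- regressOut(
      series@hbo[!isShort, , drop = FALSE],
      colMeans(series@hbo[isShort, , drop = FALSE]))
    series@hbr[!isShort, ] <- regressOut(
      series@hbr[!isShort, , drop = FALSE],
      colMeans(series@hbr[isShort, , drop = FALSE]))
    series@hbt <- series@hbo + series@hbr
  } else stop("unsupported series type")
  series
}

regressOut <- function(Y, reg) {
  if (stats::sd(reg) < .Machine$double.eps) {
    warning("superficial regressor has zero variance; regression skipped")
    return(Y)
  }
  X <- cbind(1, reg)
  t(apply(Y, 1, function(y) stats::lm.fit(X, y)$residuals))
}

pairDistances <- function(hb) {
  sqrt(rowSums((hb@probe@sourcePos[hb@pairs$source, , drop = FALSE] -
                hb@probe@detectorPos[hb@pairs$detector, , drop = FALSE])^2))
}

#' Modified Beer-Lambert conversion to hemoglobin changes
#'
#' For each source-detector pair with exactly two wavelengths, the optical
#' density changes are divided by the effective pathlength
#' \code{deff = d_cm * DPF / PVF} and the 2 x 2 extinction system is
#' inverted, yielding oxy- and deoxy-hemoglobin changes in uM.
#'
#' @param od an \code{OpticalDensity}.
#' @param params a \code{\link{beerLambertParams}} object; defaults to the
#'   probe wavelengths with the Scholkmann DPF.
#' @return a \code{\linkS4class{HemoglobinSeries}}.
#' @export
mbll <- function(od, params = NULL) {
  pr <- od@probe
  if (length(pr@wavelengths) != 2L)
    stop("mbll requires exactly 2 wavelengths per pair")
  if (is.null(params)) params <- beerLambertParams(pr@wavelengths)
  ch <- channelTable(od)
  d <- channelDistances(pr)
  pairs <- unique(ch[, c("source", "detector")])
  rownames(pairs) <- NULL
  nT <- length(od@times)
  hbo <- matrix(0, nrow(pairs), nT)
  hbr <- matrix(0, nrow(pairs), nT)
  Einv <- solve(params$extinction)
  for (p in seq_len(nrow(pairs))) {
    i1 <- which(ch$source == pairs$source[p] &
                ch$detector == pairs$detector[p] & ch$wavelength == 1L)
    i2 <- which(ch$source == pairs$source[p] &
                ch$detector == pairs$detector[p] & ch$wavelength == 2L)
    if (length(i1) != 1L || length(i2) != 1L)
      stop("pair ", pairs$source[p], "-", pairs$detector[p],
           " does not have exactly 2 wavelengths")
    deff <- effectivePathlength(d[i1] / 10, params$dpf, params$pvf)
    scaled <- rbind(od@od[i1, ] / deff[1], od@od[i2, ] / deff[2])
    hb <- Einv %*% scaled
    hbo[p, ] <- hb[1, ]
    hbr[p, ] <- hb[2, ]
  }
  new("HemoglobinSeries", probe = pr, pairs = pairs, times = od@times,
      hbo = hbo, hbr = hbr, hbt = hbo + hbr, events = od@events)
}

#' Forward Beer-Lambert synthesis
#'
#' Synthesizes per-channel optical density from known hemoglobin changes,
#' the exact inverse of \code{\link{mbll}} (useful for simulation and
#' round-trip checks).
#'
#' @param hbo,hbr pair x time matrices (uM).
#' @param probe the \code{Probe} (two wavelengths, channels covering each
#'   pair at both wavelengths).
#' @param pairs data.frame of source/detector per row of \code{hbo}.
#' @param times sample times.
#' @param params \code{\link{beerLambertParams}}.
#' @return an \code{OpticalDensity} with channels ordered as the probe.
#' @export
hbToOd <- function(hbo, hbr, probe, pairs, times, params = NULL) {
  if (is.null(params)) params <- beerLambertParams(probe@wavelengths)
  ch <- probe@channels
  d <- channelDistances(probe)
  odm <- matrix(0, nrow(ch), ncol(hbo))
  for (i in seq_len(nrow(ch))) {
    p <- which(pairs$source == ch$source[i] &
               pairs$detector == ch$detector[i])
    wl <- ch$wavelength[i]
    deff <- effectivePathlength(d[i] / 10, params$dpf[wl], params$pvf)
    eps <- params$extinction[wl, ]
    odm[i, ] <- (eps["hbo"] * hbo[p, ] + eps["hbr"] * hbr[p, ]) * deff
  }
  new("OpticalDensity", probe = probe, times = times, od = odm,
      events = data.frame(label = character(), onset = numeric(),
                          duration = numeric()),
      baselineWindow = range(times), baselineStat = "mean")
}

#' Epoch extraction and averaging
#'
#' Extracts fixed windows around each event onset (nearest-sample
#' alignment) and averages them per condition. Epochs extending beyond the
#' recording are dropped and counted.
#'
#' @param series an \code{OpticalDensity} or \code{HemoglobinSeries}; for
#'   hemoglobin input the HbO matrix is used unless \code{what} says
#'   otherwise.
#' @param events optional event table (defaults to the series events).
#' @param window numeric c(tPre, tPost) in s relative to onset (tPre
#'   negative for pre-onset samples).
#' @param baselineCorrect subtract the per-epoch pre-onset mean.
#' @param what for hemoglobin input: "hbo", "hbr" or "hbt".
#' @return a list per condition, each with elements \code{mean}, \code{sd}
#'   (channel x window-sample matrices), \code{n}, \code{dropped}, and
#'   \code{time} (window grid, s).
#' @export
epochAverage <- function(series, events = NULL, window = c(-5, 30),
                         baselineCorrect = FALSE, what = "hbo") {
  if (is.null(events)) events <- series@events
  X <- if (is(series, "HemoglobinSeries")) slot(series, what)
       else seriesMatrix(series)
  times <- series@times
  fs <- rateOf(times)
  off <- seq(round(window[1] * fs), round(window[2] * fs))
  grid <- off / fs
  out <- list()
  for (lab in unique(events$label)) {
    on <- events$onset[events$label == lab]
    idx0 <- vapply(on, function(o) which.min(abs(times - o)), integer(1))
    keep <- idx0 + min(off) >= 1L & idx0 + max(off) <= length(times)
    dropped <- sum(!keep)
    idx0 <- idx0[keep]
    if (!length(idx0))
      stop("no usable epochs for condition ", lab)
    cube <- array(NA_real_, c(nrow(X), length(off), length(idx0)))
    for (e in seq_along(idx0)) {
      seg <- X[, idx0[e] + off, drop = FALSE]
      if (baselineCorrect) {
        pre <- grid < 0
        if (any(pre)) seg <- seg - rowMeans(seg[, pre, drop = FALSE])
      }
      cube[, , e] <- seg
    }
    out[[lab]] <- list(
      mean = apply(cube, c(1, 2), mean),
      sd = apply(cube, c(1, 2), stats::sd),
      n = length(idx0), dropped = dropped, time = grid)
  }
  out
}
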