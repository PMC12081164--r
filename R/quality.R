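#' Scalp coupling index per source-detector pair
#'
#' The scalp coupling index (SCI) checks that the cardiac pulsation is seen
#' coherently at both wavelengths of a pair: both optical-density signals
#' are bandpass filtered in the cardiac band (default 0.5-2.5 Hz, zero-phase
#' third-order Butterworth) and their Pearson correlation is returned.
#' Computation is on optical density (log intensity), making the score
#' invariant to per-wavelength gain.
#'
#' @param recording an \code{OpticalRecording}.
#' @param bandLowHz,bandHighHz cardiac band edges in Hz.
#' @return data.frame with columns source, detector, sci. Pairs whose
#'   filtered signal has zero variance get \code{NA}.
#' @export
scalpCouplingIndex <- function(recording, bandLowHz = 0.5,
                               bandHighHz = 2.5) {
  fs <- samplingRate(recording)
  if (fs <= 2 * bandHighHz)
    stop("sampling rate must exceed twice the upper cardiac band edge")
  ch <- channelTable(recording)
  if (length(unique(ch$wavelength)) < 2L)
    stop("SCI requires at least 2 wavelengths")
  I <- recording@intensities
  ## optical density against the channel mean; nonpositive channels are
  ## log-undefined and yield NA
  od <- matrix(NA_real_, nrow(I), ncol(I))
  ok <- apply(I, 1, function(x) all(is.finite(x)) && all(x > 0))
  od[ok, ] <- -log10(I[ok, , drop = FALSE] /
                       rowMeans(I[ok, , drop = FALSE]))
  pairs <- unique(ch[, c("source", "detector")])
  rownames(pairs) <- NULL
  sci <- rep(NA_real_, nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    idx <- which(ch$source == pairs$source[p] &
                 ch$detector == pairs$detector[p])
    if (length(idx) < 2L) next
    idx <- idx[order(ch$wavelength[idx])][1:2]
    if (!all(ok[idx])) next
    f1 <- zeroPhaseFilter(od[idx[1], ], fs, bandLowHz, bandHighHz)
    f2 <- zeroPhaseFilter(od[idx[2], ], fs, bandLowHz, bandHighHz)
    if (stats::sd(f1) < .Machine$double.eps ||
        stats::sd(f2) < .Machine$double.eps) next
    sci[p] <- stats::cor(f1, f2)
  }
  cbind(pairs, sci = sci)
}

#' Coefficient of variation per channel
#'
#' 100 x standard deviation / mean of the raw light intensity. Channels with
#' nonpositive mean get \code{NA}.
#'
#' @param recording an \code{OpticalRecording} (raw intensities).
#' @return numeric vector of CV percentages, one per channel.
#' @export
coefficientOfVariation <- function(recording) {
  I <- recording@intensities
  m <- rowMeans(I)
  s <- apply(I, 1, stats::sd)
  cv <- 100 * s / m
  cv[m <= 0] <- NA_real_
  unname(cv)
}

#' Channel quality report
#'
#' Combines SCI, CV and the nonpositive-sample check into a per-channel
#' verdict. A channel is bad if its pair SCI falls below \code{sciMin}, its
#' CV exceeds \code{cvMax}, or it contains any sample \code{<= 0} (the
#' optical-density logarithm is undefined there).
#'
#' @param recording an \code{OpticalRecording}.
#' @param sciMin minimum acceptable SCI (correlation scale; default 0.8).
#' @param cvMax maximum acceptable CV in percent (default 30).
#' @param bandLowHz,bandHighHz cardiac band for the SCI.
#' @return data.frame with one row per channel: source, detector,
#'   wavelength, sci, cv, nonpositive, good, reason.
#' @export
channelQualityReport <- function(recording, sciMin = 0.8, cvMax = 30,
                                 bandLowHz = 0.5, bandHighHz = 2.5) {
  ch <- channelTable(recording)
  sci <- scalpCouplingIndex(recording, bandLowHz, bandHighHz)
  key <- paste(ch$source, ch$detector)
  sciPer <- sci$sci[match(key, paste(sci$source, sci$detector))]
  cv <- coefficientOfVariation(recording)
  nonpos <- apply(recording@intensities, 1,
                  function(x) any(!is.finite(x)) || any(x <= 0))
  reason <- character(nrow(ch))
  bad <- rep(FALSE, nrow(ch))
  flag <- function(cond, why) {
    add <- cond & !is.na(cond)
    reason[add] <<- ifelse(nzchar(reason[add]),
                           paste(reason[add], why, sep = ";"), why)
    bad <<- bad | add
  }
  flag(nonpos, "nonpositive")
  flag(is.na(sciPer) | sciPer < sciMin, "sci")
  flag(is.na(cv) | cv > cvMax, "cv")
  data.frame(channel = seq_len(nrow(ch)), source = ch$source,
             detector = ch$detector, wavelength = ch$wavelength,
             sci = sciPer, cv = cv, nonpositive = nonpos,
             good = !bad, reason = reason)
}

#' Flag bad channels on a recording
#'
#' Applies the quality thresholds and updates the recording's channel flags;
#' the data are untouched, so the operation is idempotent.
#'
#' @inheritParams channelQualityReport
#' @return the recording with updated \code{channelFlags}.
#' @export
pruneChannels <- function(recording, sciMin = 0.8, cvMax = 30,
                          bandLowHz = 0.5, bandHighHz = 2.5) {
  rep <- channelQualityReport(recording, sciMin, cvMax, bandLowHz,
                              bandHighHz)
  recording@channelFlags <- data.frame(good = rep$good, reason = rep$reason)
  recording
}

#' Write a quality report as TSV
#'
#' @param report output of \code{channelQualityReport}.
#' @param path output path.
#' @export
writeQualityReport <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
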