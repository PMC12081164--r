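#' @include AllClasses.R
NULL

#' Accessors for probe and recording objects
#'
#' \code{probe}, \code{samplingRate}, \code{channelTable}, \code{events},
#' \code{channelDistances}, \code{nChannels} extract the corresponding
#' component; \code{intensities} and \code{seriesMatrix} return the data
#' matrix of a recording or optical-density series.
#'
#' @param object a \code{Probe}, \code{OpticalRecording},
#'   \code{OpticalDensity} or \code{HemoglobinSeries}.
#' @return the extracted component.
#' @name accessors
#' @aliases probe samplingRate channelTable seriesMatrix
NULL

#' @rdname accessors
#' @export
setGeneric("probe", function(object) standardGeneric("probe"))

#' @rdname accessors
#' @export
setGeneric("channelTable", function(object) standardGeneric("channelTable"))

#' @rdname accessors
#' @export
setGeneric("events", function(object) standardGeneric("events"))

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))

#' @rdname accessors
#' @export
setGeneric("seriesMatrix", function(object) standardGeneric("seriesMatrix"))

#' @rdname accessors
#' @export
setGeneric("channelDistances",
           function(object) standardGeneric("channelDistances"))

#' @rdname accessors
#' @export
setGeneric("nChannels", function(object) standardGeneric("nChannels"))

#' @rdname accessors
#' @export
setGeneric("channelFlags", function(object) standardGeneric("channelFlags"))

#' @rdname accessors
#' @export
setMethod("probe", "OpticalRecording", function(object) object@probe)
#' @rdname accessors
#' @export
setMethod("probe", "OpticalDensity", function(object) object@probe)
#' @rdname accessors
#' @export
setMethod("probe", "HemoglobinSeries", function(object) object@probe)

#' @rdname accessors
#' @export
setMethod("channelTable", "Probe", function(object) object@channels)
#' @rdname accessors
#' @export
setMethod("channelTable", "OpticalRecording",
          function(object) object@probe@channels)
#' @rdname accessors
#' @export
setMethod("channelTable", "OpticalDensity",
          function(object) object@probe@channels)

#' @rdname accessors
#' @export
setMethod("events", "OpticalRecording", function(object) object@events)
#' @rdname accessors
#' @export
setMethod("events", "OpticalDensity", function(object) object@events)
#' @rdname accessors
#' @export
setMethod("events", "HemoglobinSeries", function(object) object@events)

rateOf <- function(times) {
  if (length(times) < 2L) stop("need at least two samples")
  1 / stats::median(diff(times))
}

#' @rdname accessors
#' @export
setMethod("samplingRate", "OpticalRecording",
          function(object) rateOf(object@times))
#' @rdname accessors
#' @export
setMethod("samplingRate", "OpticalDensity",
          function(object) rateOf(object@times))
#' @rdname accessors
#' @export
setMethod("samplingRate", "HemoglobinSeries",
          function(object) rateOf(object@times))

#' @rdname accessors
#' @export
setMethod("intensities", "OpticalRecording", function(object) object@intensities)

#' @rdname accessors
#' @export
setMethod("seriesMatrix", "OpticalRecording",
          function(object) object@intensities)
#' @rdname accessors
#' @export
setMethod("seriesMatrix", "OpticalDensity", function(object) object@od)

#' @rdname accessors
#' @export
setMethod("channelDistances", "Probe", function(object) {
  ch <- object@channels
  sqrt(rowSums((object@sourcePos[ch$source, , drop = FALSE] -
                object@detectorPos[ch$detector, , drop = FALSE])^2))
})
#' @rdname accessors
#' @export
setMethod("channelDistances", "OpticalRecording",
          function(object) channelDistances(object@probe))
#' @rdname accessors
#' @export
setMethod("channelDistances", "OpticalDensity",
          function(object) channelDistances(object@probe))

#' @rdname accessors
#' @export
setMethod("nChannels", "Probe", function(object) nrow(object@channels))
#' @rdname accessors
#' @export
setMethod("nChannels", "OpticalRecording",
          function(object) nrow(object@probe@channels))
#' @rdname accessors
#' @export
setMethod("nChannels", "OpticalDensity",
          function(object) nrow(object@probe@channels))

#' @rdname accessors
#' @export
setMethod("channelFlags", "OpticalRecording",
          function(object) object@channelFlags)

setMethod("show", "Probe", function(object) {
  cat(sprintf(
    "Probe: %d sources, %d detectors, %d wavelengths (%s nm), %d channels\n",
    nrow(object@sourcePos), nrow(object@detectorPos),
    length(object@wavelengths),
    paste(object@wavelengths, collapse = "/"), nrow(object@channels)))
  if (!is.null(object@landmarks))
    cat("  landmarks:", paste(rownames(object@landmarks), collapse = ", "),
        "\n")
})

setMethod("show", "OpticalRecording", function(object) {
  cat(sprintf(
    "OpticalRecording: %d channels x %d samples at %.3g Hz, %d events\n",
    nrow(object@intensities), ncol(object@intensities),
    if (length(object@times) > 1) rateOf(object@times) else NA_real_,
    nrow(object@events)))
  bad <- sum(!object@channelFlags$good)
  if (bad) cat(sprintf("  %d channel(s) flagged bad\n", bad))
})

setMethod("show", "OpticalDensity", function(object) {
  cat(sprintf("OpticalDensity: %d channels x %d samples (baseline %s over [%g, %g] s)\n",
              nrow(object@od), ncol(object@od), object@baselineStat,
              object@baselineWindow[1], object@baselineWindow[2]))
})

setMethod("show", "HemoglobinSeries", function(object) {
  cat(sprintf("HemoglobinSeries: %d pairs x %d samples (uM)\n",
              nrow(object@hbo), ncol(object@hbo)))
})

setMethod("show", "CorticalSurface", function(object) {
  cat(sprintf("CorticalSurface: %d vertices, %d faces\n",
              nrow(object@vertices), nrow(object@faces)))
})

setMethod("show", "HeadVolume", function(object) {
  d <- dim(object@labels)
  cat(sprintf("HeadVolume: %d x %d x %d voxels at %g mm\n",
              d[1], d[2], d[3], object@voxelSize))
})

setMethod("show", "ForwardModel", function(object) {
  cat(sprintf("ForwardModel: %d channels x %d field-of-view vertices\n",
              nrow(object@A), ncol(object@A)))
})

setMethod("show", "Parcellation", function(object) {
  cat(sprintf("Parcellation: %d parcels over %d vertices (radius %.2f mm)\n",
              length(object@parcels), length(object@assignment),
              object@neighborhoodOrder))
})

setMethod("show", "MEMSolution", function(object) {
  cat(sprintf("MEMSolution: %d vertices x %d samples; %d/%d samples converged\n",
              nrow(object@j), ncol(object@j), sum(object@converged),
              length(object@converged)))
})

setMethod("show", "GLMResult", function(object) {
  cat(sprintf("GLMResult: %d regressors x %d channels (serial: %s, dof %.1f)\n",
              nrow(object@beta), ncol(object@beta), object@serial,
              object@dof[1]))
})

setMethod("show", "MontageSolution", function(object) {
  cat(sprintf("MontageSolution (%s): %d sources, %d detectors, %d channels, objective %.6g\n",
              object@status, length(object@sources),
              length(object@detectors), nrow(object@channels),
              object@objective))
})
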